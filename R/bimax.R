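# Distinct pathways covered by a set of item row names ("P:up"/"P:down").
.itemPathways <- function(items) unique(sub(":(up|down)$", "", items))

# Canonical bicluster ordering: most samples first, then most items, then
# lexicographic item key.
.orderBiclusters <- function(bcs) {
  if (!length(bcs)) return(bcs)
  ns <- vapply(bcs, function(b) length(b$samples), 0L)
  ni <- vapply(bcs, function(b) length(b$items), 0L)
  key <- vapply(bcs, function(b) paste(b$items, collapse = "|"), "")
  bcs[order(-ns, -ni, key)]
}

#' Enumerate inclusion-maximal all-ones submatrices of a binary matrix
#'
#' Maximal biclusters are exactly the closed itemsets of the matrix (the
#' itemset is every row that is 1 on all columns of its cover; the cover is
#' every column that is 1 on all rows of the itemset); they are enumerated
#' once each by depth-first search with prefix-preserving closure
#' extensions, pruning covers below `minSamples` (cover size is
#' anti-monotone in the itemset). Row names of the form `"P:up"`/`"P:down"`
#' are grouped into pathways for the `minPathways` constraint; any other
#' row name counts as its own pathway.
#'
#' @param bits 0/1 matrix with row and column names.
#' @param minPathways minimum distinct pathways per bicluster.
#' @param minSamples minimum number of supporting samples.
#' @return list of biclusters (`items`, `pathways`, `samples`) in
#'   canonical order (most samples, then most items, then lexicographic
#'   items).
#' @export
maximalBiclusters <- function(bits, minPathways = 2, minSamples = 1) {
  items <- rownames(bits)
  nI <- nrow(bits)
  out <- list()
  storage.mode(bits) <- "integer"

  closure <- function(coverIdx) {
    which(rowSums(bits[, coverIdx, drop = FALSE]) == length(coverIdx))
  }
  record <- function(itemIdx, coverIdx) {
    if (length(coverIdx) >= minSamples && length(itemIdx) &&
        length(.itemPathways(items[itemIdx])) >= minPathways) {
      out[[length(out) + 1L]] <<- list(
        items = sort(items[itemIdx]),
        pathways = sort(.itemPathways(items[itemIdx])),
        samples = sort(colnames(bits)[coverIdx]))
    }
  }
  dfs <- function(itemIdx, coverIdx, lastItem) {
    record(itemIdx, coverIdx)
    for (i in seq_len(nI)) {
      if (i <= lastItem || i %in% itemIdx) next
      newCover <- coverIdx[bits[i, coverIdx] == 1L]
      if (length(newCover) < minSamples) next
      q <- closure(newCover)
      # prefix-preserving check: the closure may only add items beyond i
      if (any(q < i & !(q %in% itemIdx))) next
      dfs(q, newCover, i)
    }
  }
  allCover <- seq_len(ncol(bits))
  if (length(allCover) >= minSamples) {
    root <- closure(allCover)
    dfs(root, allCover, 0L)
  }
  .orderBiclusters(out)
}

#' BiMax biclustering of a binary transaction matrix
#'
#' Enumerates every inclusion-maximal all-ones submatrix (bicluster) of one
#' class's columns of the 2n-item up/down matrix, subject to covering at
#' least `minPathways` distinct pathways and at least
#' `ceil(minSupport * n_class)` of the class's samples. An up and a down
#' item of the same pathway can never co-occur in a bicluster because no
#' sample carries both bits. Mining runs separately per class; call once
#' per class.
#'
#' @param btm a [BinaryTransactionMatrix-class].
#' @param class `"case"` or `"control"`: the class whose samples are mined.
#' @param minPathways minimum distinct pathways per bicluster (default 2).
#' @param minSupport minimum fraction of the class's samples a bicluster
#'   must cover, in (0, 1] (default 0.25).
#' @return list of biclusters, each a list with `items`, `pathways`,
#'   `samples` and `class`, in canonical order (most samples first, then
#'   most items, then lexicographic items).
#' @export
bimax <- function(btm, class = c("case", "control"), minPathways = 2,
                  minSupport = 0.25) {
  class <- match.arg(class)
  stopifnot(is(btm, "BinaryTransactionMatrix"))
  if (minSupport <= 0 || minSupport > 1)
    stop("minSupport must be in (0, 1]")
  cols <- sampleLabels(btm) == class
  if (!any(cols)) stop("no ", class, " samples in the matrix")
  sub <- transactionBits(btm)[, cols, drop = FALSE]
  minSamples <- ceiling(minSupport * sum(cols))
  bcs <- maximalBiclusters(sub, minPathways, minSamples)
  lapply(bcs, function(b) c(b, list(class = class)))
}

#' Brute-force bicluster oracle
#'
#' Exhaustively enumerates every non-empty item subset, pairs it with the
#' intersection of its supporting samples, keeps pairs meeting the
#' thresholds, and retains the inclusion-maximal ones (no kept pair may
#' extend another in both items and samples). Exponential in the item
#' count; refuses more than 16 items. Intended as an independent test
#' oracle for [bimax()].
#'
#' @param bits 0/1 matrix with item row names and sample column names.
#' @param minPathways minimum distinct pathways per bicluster.
#' @param minSamples minimum number of supporting samples.
#' @return list of biclusters (`items`, `pathways`, `samples`) in the same
#'   canonical order as [bimax()].
#' @export
bruteForceBiclusters <- function(bits, minPathways = 2, minSamples = 1) {
  nI <- nrow(bits)
  if (nI > 16L) stop("brute force limited to 16 items")
  items <- rownames(bits)
  storage.mode(bits) <- "integer"
  # every non-empty item subset as a bitmask membership matrix
  nSub <- 2L^nI - 1L
  memb <- outer(seq_len(nSub), seq_len(nI), function(s, i)
    bitwAnd(s, bitwShiftL(1L, i - 1L)) > 0L)
  sizes <- rowSums(memb)
  covered <- (memb %*% bits) == sizes          # subset x sample
  sampCount <- rowSums(covered)
  cand <- which(sampCount >= minSamples)
  pwOfItem <- sub(":(up|down)$", "", items)
  cand <- cand[vapply(cand, function(s)
    length(unique(pwOfItem[memb[s, ]])), 0L) >= minPathways]
  if (!length(cand)) return(list())
  # retain inclusion-maximal pairs: a kept pair is dominated only by a
  # strict item superset with the same covered samples (an item superset
  # can never enlarge the cover)
  coverKey <- apply(covered[cand, , drop = FALSE], 1L, paste,
                    collapse = "")
  dominated <- logical(length(cand))
  for (grp in split(seq_along(cand), coverKey)) {
    if (length(grp) < 2L) next
    for (i in grp) {
      dominated[i] <- any(vapply(grp, function(j) {
        j != i && sizes[cand[j]] > sizes[cand[i]] &&
          all(memb[cand[j], ] | !memb[cand[i], ])
      }, TRUE))
    }
  }
  maximal <- cand[!dominated]
  .orderBiclusters(lapply(maximal, function(s) list(
    items = sort(items[memb[s, ]]),
    pathways = sort(unique(pwOfItem[memb[s, ]])),
    samples = sort(colnames(bits)[covered[s, ]]))))
}
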
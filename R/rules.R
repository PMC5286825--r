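# Canonical string key for an itemset.
.itemKey <- function(items) paste(sort(items), collapse = "|")

#' Support, confidence and lift of a pathway-set rule
#'
#' All three metrics are ratios of integer counts over all N samples:
#' `cover` = samples where every item bit is 1, `a` = covered samples of
#' the consequent class; support = a/N, confidence = a/|cover|,
#' lift = confidence / (n_class/N).
#'
#' @param itemset character vector of item names (rows of `btm`).
#' @param btm the full-class [BinaryTransactionMatrix-class].
#' @param class consequent class, `"case"` or `"control"`.
#' @return list with `support`, `confidence`, `lift` and the integer counts
#'   `nCover`, `nCoverClass`, `nClass`, `nTotal`.
#' @export
ruleMetrics <- function(itemset, btm, class = c("case", "control")) {
  class <- match.arg(class)
  stopifnot(is(btm, "BinaryTransactionMatrix"))
  if (!length(itemset)) stop("empty itemset")
  bits <- transactionBits(btm)
  missingI <- setdiff(itemset, rownames(bits))
  if (length(missingI))
    stop("unknown item(s): ", paste(missingI, collapse = ", "))
  labels <- sampleLabels(btm)
  cover <- colSums(bits[itemset, , drop = FALSE] == 1) == length(itemset)
  nCover <- sum(cover)
  if (nCover == 0) stop("itemset covers no sample")
  a <- sum(cover & labels == class)
  N <- length(labels)
  nClass <- sum(labels == class)
  list(support = a / N,
       confidence = a / nCover,
       lift = (a * N) / (nCover * nClass),
       nCover = nCover, nCoverClass = a, nClass = nClass, nTotal = N)
}

#' Generate association rules from per-class biclusters
#'
#' Each bicluster itemset yields one candidate rule
#' `{itemset} => {mined class}`; rules are kept when confidence >= `minConf`
#' and lift > `minLift`, with both boundaries decided on the underlying
#' integer counts (confidence exactly at the threshold passes; lift exactly
#' at the threshold fails). Duplicate (itemset, class) candidates from
#' different biclusters collapse to one rule.
#'
#' @param biclusters list of biclusters from [bimax()] (possibly
#'   concatenated across classes; each carries its mined class).
#' @param btm the full [BinaryTransactionMatrix-class].
#' @param minConf minimum confidence, inclusive (default 0.8).
#' @param minLift minimum lift, exclusive (default 1).
#' @return data.frame with columns itemset (canonical `|`-joined key),
#'   items (list column), class, support, confidence, lift, nCover,
#'   nCoverClass.
#' @export
generateRules <- function(biclusters, btm, minConf = 0.8, minLift = 1) {
  if (minConf < 0 || minConf > 1) stop("minConf must be in [0, 1]")
  if (minLift < 0) stop("minLift must be non-negative")
  if (!length(biclusters)) return(.emptyRules())
  keys <- vapply(biclusters, function(b)
    paste(b$class, .itemKey(b$items), sep = "@"), "")
  biclusters <- biclusters[!duplicated(keys)]
  rows <- lapply(biclusters, function(b) {
    m <- ruleMetrics(b$items, btm, b$class)
    # integer-count boundary semantics: a/c >= minConf and
    # a*N/(c*nClass) > minLift, decided with a tolerance that cannot flip
    # a genuine rational boundary
    passConf <- m$nCoverClass >= minConf * m$nCover - 1e-9
    passLift <- m$nCoverClass * m$nTotal >
      minLift * m$nCover * m$nClass + 1e-9
    if (!(passConf && passLift)) return(NULL)
    data.frame(itemset = .itemKey(b$items), class = b$class,
               support = m$support, confidence = m$confidence,
               lift = m$lift, nCover = m$nCover,
               nCoverClass = m$nCoverClass, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(.emptyRules())
  out <- do.call(rbind, rows)
  out$items <- strsplit(out$itemset, "|", fixed = TRUE)
  rownames(out) <- NULL
  out[order(out$class, out$itemset), ]
}

.emptyRules <- function() {
  out <- data.frame(itemset = character(), class = character(),
                    support = numeric(), confidence = numeric(),
                    lift = numeric(), nCover = integer(),
                    nCoverClass = integer(), stringsAsFactors = FALSE)
  out$items <- list()
  out
}

#' Resolve itemsets found in both classes
#'
#' When the same itemset produced a case rule and a control rule, only the
#' more significant one survives: higher lift wins, then higher confidence,
#' then higher support; a full tie keeps the case rule (with a warning).
#'
#' @param rules data.frame from [generateRules()].
#' @return filtered rules data.frame.
#' @export
deduplicateCrossClass <- function(rules) {
  if (!nrow(rules)) return(rules)
  drop <- logical(nrow(rules))
  dup <- split(seq_len(nrow(rules)), rules$itemset)
  for (idx in dup) {
    if (length(idx) < 2L) next
    r <- rules[idx, ]
    ord <- order(-r$lift, -r$confidence, -r$support,
                 match(r$class, c("case", "control")))
    if (r$lift[ord[1L]] == r$lift[ord[2L]] &&
        r$confidence[ord[1L]] == r$confidence[ord[2L]] &&
        r$support[ord[1L]] == r$support[ord[2L]]) {
      warning("cross-class tie for itemset '", r$itemset[1L],
              "'; keeping the case rule")
    }
    drop[idx[ord[-1L]]] <- TRUE
  }
  out <- rules[!drop, ]
  rownames(out) <- NULL
  out
}

#' Rank rules by interestingness and select top-n markers per class
#'
#' Within each class, rules are sorted by lift (descending), then
#' confidence, support, itemset size (all descending), then lexicographic
#' itemset key, and the first `topN` become the class's pathway-set
#' markers. Classes with fewer rules keep them all (with a message).
#'
#' @param rules data.frame from [generateRules()] /
#'   [deduplicateCrossClass()].
#' @param topN markers per class (default 250).
#' @return rules data.frame with an added `rank` column (1-based within
#'   class), restricted to the selected markers.
#' @export
rankAndSelect <- function(rules, topN = 250) {
  if (topN < 1) stop("topN must be at least 1")
  if (!nrow(rules)) return(cbind(rules, rank = integer()))
  pieces <- lapply(split(rules, rules$class), function(r) {
    size <- lengths(r$items)
    ord <- order(-r$lift, -r$confidence, -r$support, -size, r$itemset)
    sel <- head(ord, topN)
    if (length(ord) < topN) {
      message("class ", r$class[1L], ": only ", length(ord),
              " rules available for topN = ", topN)
    }
    out <- r[sel, ]
    out$rank <- seq_along(sel)
    out
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Run the full marker-mining stage
#'
#' Convenience wrapper: per-class [bimax()], [generateRules()],
#' [deduplicateCrossClass()] and [rankAndSelect()].
#'
#' @inheritParams bimax
#' @inheritParams generateRules
#' @inheritParams rankAndSelect
#' @return ranked marker data.frame (see [rankAndSelect()]).
#' @export
minePathwaySetMarkers <- function(btm, minPathways = 2, minSupport = 0.25,
                                  minConf = 0.8, minLift = 1, topN = 250) {
  bcs <- c(bimax(btm, "case", minPathways, minSupport),
           bimax(btm, "control", minPathways, minSupport))
  rules <- generateRules(bcs, btm, minConf, minLift)
  rankAndSelect(deduplicateCrossClass(rules), topN)
}

#' Write markers to JSON
#'
#' @param markers marker data.frame from [rankAndSelect()].
#' @param path output path.
#' @export
writeMarkersJSON <- function(markers, path) {
  recs <- lapply(seq_len(nrow(markers)), function(i) list(
    itemset = markers$items[[i]],
    class = markers$class[i],
    support = markers$support[i],
    confidence = markers$confidence[i],
    lift = markers$lift[i],
    rank = markers$rank[i]))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
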
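#' Signal-to-noise ratio ranking metric
#'
#' `(mean(case) - mean(control)) / (sd(case) + sd(control))`, where each
#' group standard deviation is floored at `max(0.2 * |group mean|, 1e-8)`
#' (the GSEA desktop convention) so that near-constant genes cannot blow up
#' the ratio.
#'
#' @param caseValues,controlValues numeric vectors, each of length >= 2.
#' @return the SNR statistic.
#' @export
snrScore <- function(caseValues, controlValues) {
  if (length(caseValues) < 2L || length(controlValues) < 2L)
    stop("each group needs at least 2 values")
  s1 <- max(sd(caseValues), 0.2 * abs(mean(caseValues)), 1e-8)
  s2 <- max(sd(controlValues), 0.2 * abs(mean(controlValues)), 1e-8)
  (mean(caseValues) - mean(controlValues)) / (s1 + s2)
}

#' Welch two-sample t ranking metric
#'
#' @inheritParams snrScore
#' @return the Welch t statistic (case minus control).
#' @export
tstatScore <- function(caseValues, controlValues) {
  if (length(caseValues) < 2L || length(controlValues) < 2L)
    stop("each group needs at least 2 values")
  se <- sqrt(var(caseValues) / length(caseValues) +
             var(controlValues) / length(controlValues))
  (mean(caseValues) - mean(controlValues)) / max(se, 1e-12)
}

# Row-wise group means/variances for many label permutations at once.
# values: genes x samples; caseInd: samples x P 0/1 indicator of case
# membership (group sizes constant across columns). Returns genes x P
# metric matrices computed with BLAS-level operations.
.rowMetricMatrix <- function(values, caseInd, metric = c("snr", "tstat")) {
  metric <- match.arg(metric)
  n1 <- sum(caseInd[, 1L])
  n2 <- nrow(caseInd) - n1
  s1 <- values %*% caseInd
  sq1 <- (values^2) %*% caseInd
  rs <- rowSums(values)
  rsq <- rowSums(values^2)
  m1 <- s1 / n1
  m2 <- (rs - s1) / n2
  v1 <- pmax((sq1 - n1 * m1^2) / (n1 - 1), 0)
  v2 <- pmax(((rsq - sq1) - n2 * m2^2) / (n2 - 1), 0)
  if (metric == "snr") {
    sd1 <- pmax(sqrt(v1), 0.2 * abs(m1), 1e-8)
    sd2 <- pmax(sqrt(v2), 0.2 * abs(m2), 1e-8)
    (m1 - m2) / (sd1 + sd2)
  } else {
    (m1 - m2) / pmax(sqrt(v1 / n1 + v2 / n2), 1e-12)
  }
}

# Enrichment score from hit positions. pos: 1-based positions of the set's
# genes in the ranking; w: |metric|^p weights of those genes; N: total
# ranked genes. The running sum's extrema occur immediately before/after
# hits, so only 2k candidate values are examined.
.esFromPositions <- function(pos, w, N) {
  k <- length(pos)
  o <- order(pos)
  p <- pos[o]
  w <- w[o]
  sw <- sum(w)
  cumw <- if (sw > 0) cumsum(w) / sw else seq_len(k) / k
  miss <- (p - seq_len(k)) / (N - k)
  after <- cumw - miss
  before <- c(0, cumw[-k]) - miss
  hi <- max(after)
  lo <- min(before)
  if (hi >= -lo) hi else lo
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked gene list; member-gene hits increment the running sum by
#' `|metric|^p` normalized by the total hit weight, misses decrement it by
#' `1/(N - Nh)`. The score is the running-sum value of maximum absolute
#' deviation from zero, signed (ties between an equal positive and negative
#' excursion resolve to the positive one).
#'
#' @param rankedMetric named numeric vector of ranking-metric values; it is
#'   sorted in decreasing order internally.
#' @param geneSet character vector of member genes.
#' @param weightExponent exponent `p` applied to `|metric|` at hits
#'   (default 1).
#' @return the enrichment score, in `[-1, 1]`.
#' @export
gseaEnrichmentScore <- function(rankedMetric, geneSet, weightExponent = 1) {
  stopifnot(!is.null(names(rankedMetric)))
  m <- sort(rankedMetric, decreasing = TRUE)
  hit <- names(m) %in% geneSet
  if (!any(hit)) stop("gene set has no member in the ranked list")
  if (all(hit)) stop("gene set covers the whole ranked list")
  pos <- which(hit)
  .esFromPositions(pos, abs(m[pos])^weightExponent, length(m))
}

#' Permutation-based gene-set enrichment analysis
#'
#' For every gene set, genes are ranked by a class-contrast metric (SNR or
#' Welch t) and scored with the weighted KS enrichment score; significance
#' comes from phenotype-label permutations: the empirical two-sided p-value
#' is `(1 + #{|ES_perm| >= |ES_obs|}) / (1 + nPerm)`, and q-values are
#' Benjamini-Hochberg adjusted across sets. Sets with fewer than `minSize`
#' members present in the matrix are skipped (with a message).
#'
#' @param x an [OmicsMatrix-class] (typically z-score normalized).
#' @param gsc a [GeneSetCollection-class].
#' @param metric `"snr"` or `"tstat"`.
#' @param nPerm number of label permutations (>= 100).
#' @param seed integer seed for the permutations.
#' @param weightExponent hit-weight exponent (default 1).
#' @param minSize minimum member genes present in the matrix (default 5).
#' @return data.frame with columns pathway, size, ES, p, q, metric, and
#'   attributes `nPerm` and `seed`.
#' @export
permutationEnrichment <- function(x, gsc, metric = c("snr", "tstat"),
                                  nPerm = 1000, seed = 1,
                                  weightExponent = 1, minSize = 5) {
  metric <- match.arg(metric)
  stopifnot(is(x, "OmicsMatrix"), is(gsc, "GeneSetCollection"))
  if (nPerm < 100) stop("nPerm must be at least 100")
  values <- omicsValues(x)
  labels <- sampleLabels(x)
  genes <- rownames(values)
  N <- length(genes)
  idx <- lapply(geneSets(gsc), function(g) which(genes %in% g))
  keep <- lengths(idx) >= minSize & lengths(idx) < N
  if (any(!keep)) {
    message(sum(!keep), " set(s) skipped (fewer than ", minSize,
            " member genes in the matrix, or all genes)")
  }
  idx <- idx[keep]
  if (!length(idx)) stop("no gene set with enough member genes in the matrix")

  nSamp <- length(labels)
  nCase <- sum(labels == "case")
  obs <- as.integer(labels == "case")
  nDistinct <- choose(nSamp, nCase)
  set.seed(seed)
  if (nDistinct - 1 < nPerm) {
    warning("only ", nDistinct - 1, " distinct label permutations exist; ",
            "using all of them")
    combs <- combn(nSamp, nCase)
    perms <- matrix(0L, nSamp, ncol(combs))
    perms[cbind(as.vector(combs),
                rep(seq_len(ncol(combs)), each = nCase))] <- 1L
    perms <- perms[, colSums(perms != obs) > 0, drop = FALSE]
  } else {
    perms <- vapply(seq_len(nPerm), function(i) {
      p <- integer(nSamp)
      p[sample.int(nSamp, nCase)] <- 1L
      p
    }, integer(nSamp))
  }
  nPermUsed <- ncol(perms)

  ind <- cbind(obs, perms)
  mm <- .rowMetricMatrix(values, ind, metric)
  absm <- abs(mm)^weightExponent
  # position of gene g in the decreasing ranking of column j
  rk <- apply(-mm, 2L, rank, ties.method = "first")

  nSets <- length(idx)
  esObs <- numeric(nSets)
  pval <- numeric(nSets)
  for (s in seq_len(nSets)) {
    g <- idx[[s]]
    es <- vapply(seq_len(ncol(ind)), function(j)
      .esFromPositions(rk[g, j], absm[g, j], N), 0)
    esObs[s] <- es[1L]
    pval[s] <- (1 + sum(abs(es[-1L]) >= abs(es[1L]))) / (1 + nPermUsed)
  }
  res <- data.frame(pathway = names(idx), size = lengths(idx),
                    ES = esObs, p = pval,
                    q = p.adjust(pval, method = "BH"),
                    metric = metric, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(res, "nPerm") <- nPermUsed
  attr(res, "seed") <- seed
  res
}

#' Intersect SNR- and t-significant pathways
#'
#' Pathways with FDR q below `qThreshold` under both ranking metrics, sorted
#' by the larger of the two q-values (most confidently significant first).
#'
#' @param resSnr,resT results from [permutationEnrichment()] over the same
#'   collection with metrics `"snr"` and `"tstat"`.
#' @param qThreshold FDR cutoff (default 0.05).
#' @return character vector of pathway IDs.
#' @export
selectSignificantPathways <- function(resSnr, resT, qThreshold = 0.05) {
  sigS <- resSnr$pathway[resSnr$q < qThreshold]
  sigT <- resT$pathway[resT$q < qThreshold]
  common <- intersect(sigS, sigT)
  if (!length(common)) {
    message("no pathway significant under both metrics at q < ", qThreshold)
    return(character())
  }
  qmax <- pmax(resSnr$q[match(common, resSnr$pathway)],
               resT$q[match(common, resT$pathway)])
  common[order(qmax, common)]
}

#' Union of significant pathways across data types
#'
#' Combines the significant pathways found from expression data with those
#' found from methylation data: deduplicated union in lexicographic order.
#'
#' @param exprSig,methSig character vectors of pathway IDs.
#' @return sorted character vector.
#' @export
unionAcrossDatatypes <- function(exprSig, methSig) {
  sort(union(exprSig, methSig))
}
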
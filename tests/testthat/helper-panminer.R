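# Shared fixtures and independent oracles, all built in code.

# Quick labelled matrix: nCase + nControl samples of iid N(0,1) rows.
makeOmics <- function(nGenes = 10, nCase = 5, nControl = 5, seed = 1,
                      datatype = "expression") {
  set.seed(seed)
  n <- nCase + nControl
  m <- matrix(rnorm(nGenes * n), nGenes, n,
              dimnames = list(sprintf("G%03d", seq_len(nGenes)),
                              sprintf("S%02d", seq_len(n))))
  OmicsMatrix(m, rep(c("case", "control"), c(nCase, nControl)), datatype)
}

labelsFor <- function(nCase, nControl) {
  setNames(rep(c("case", "control"), c(nCase, nControl)),
           c(sprintf("Case%02d", seq_len(nCase)),
             sprintf("Ctrl%02d", seq_len(nControl))))
}

# Build a PathwayActivityProfile directly from an activity matrix.
makeProfile <- function(activities, labels, datatype = "expression") {
  corg <- setNames(lapply(rownames(activities), function(p)
    setNames(1, paste0(p, "_G1"))), rownames(activities))
  new("PathwayActivityProfile", activities = activities, corg = corg,
      labels = factor(labels, levels = c("case", "control")),
      datatype = datatype)
}

makeStates <- function(states, labels) {
  new("DiscretizedActivity", states = states,
      labels = factor(labels, levels = c("case", "control")))
}

# Independent O(N) running-sum oracle for the weighted KS enrichment
# score: walk the full ranked list and track the extreme deviation.
naiveRunningSumES <- function(rankedMetric, geneSet, weightExponent = 1) {
  m <- sort(rankedMetric, decreasing = TRUE)
  hit <- names(m) %in% geneSet
  w <- abs(m)^weightExponent
  sw <- sum(w[hit])
  inc <- ifelse(hit, if (sw > 0) w / sw else 1 / sum(hit),
                -1 / (length(m) - sum(hit)))
  rs <- cumsum(inc)
  rs[which.max(abs(rs))]
}

# Random 0/1 item-by-sample matrix at a given density.
randomBits <- function(nItems, nSamples, density, seed) {
  set.seed(seed)
  matrix(rbinom(nItems * nSamples, 1, density), nItems, nSamples,
         dimnames = list(sprintf("r%02d", seq_len(nItems)),
                         sprintf("c%02d", seq_len(nSamples))))
}

# Direct verification that a bicluster is all-ones and inclusion-maximal
# in `bits` (no extra item keeps the sample set all-ones, no extra sample
# keeps the item set all-ones).
isMaximalAllOnes <- function(bits, items, samples) {
  sub <- bits[items, samples, drop = FALSE]
  if (!all(sub == 1)) return(FALSE)
  others <- setdiff(rownames(bits), items)
  if (length(others) &&
      any(rowSums(bits[others, samples, drop = FALSE]) == length(samples)))
    return(FALSE)
  otherS <- setdiff(colnames(bits), samples)
  if (length(otherS) &&
      any(colSums(bits[items, otherS, drop = FALSE]) == length(items)))
    return(FALSE)
  TRUE
}

bcKey <- function(b) paste(paste(b$items, collapse = "|"),
                           paste(b$samples, collapse = "|"), sep = "@")

# Exhaustive oracle for the condition-responsive subset: evaluate the
# |t| of the sign-aligned combined activity for every non-empty member
# subset and return the maximum.
exhaustiveBestT <- function(om, genes) {
  labels <- sampleLabels(om)
  isCase <- labels == "case"
  v <- omicsValues(om)[genes, , drop = FALSE]
  z <- (v - rowMeans(v)) / apply(v, 1, sd)
  tsign <- sign(apply(z, 1, function(r) tstatScore(r[isCase], r[!isCase])))
  tsign[tsign == 0] <- 1
  best <- -Inf
  for (k in seq_along(genes)) {
    for (sub in combn(seq_along(genes), k, simplify = FALSE)) {
      a <- colSums(z[sub, , drop = FALSE] * tsign[sub]) / sqrt(k)
      best <- max(best, abs(tstatScore(a[isCase], a[!isCase])))
    }
  }
  best
}

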
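# Row-wise z-scores; constant rows become all-zero rather than NaN so a
# degenerate member cannot poison a combined activity.
.zscoreRows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  s[s == 0] <- 1
  list(z = (m - mu) / s, center = mu, scale = s)
}

# Greedy condition-responsive combination shared by gene-level and
# pathway-level activity inference. zrows: signed, z-scored feature rows in
# the order they should be tried (most discriminative first). Accepts a
# feature while the absolute discriminative score of the running average
# a_S = rowSums(z_S)/sqrt(|S|) strictly increases, and stops at the first
# failure.
.greedyCombine <- function(zrows, scoreFun) {
  k <- nrow(zrows)
  acc <- zrows[1L, ]
  taken <- 1L
  score <- abs(scoreFun(acc))
  trajectory <- score
  if (k > 1L) {
    for (i in 2L:k) {
      sum2 <- acc * sqrt(length(taken)) + zrows[i, ]
      cand <- sum2 / sqrt(length(taken) + 1L)
      cs <- abs(scoreFun(cand))
      if (cs > score) {
        acc <- cand
        taken <- c(taken, i)
        score <- cs
        trajectory <- c(trajectory, cs)
      } else {
        break
      }
    }
  }
  list(activity = acc, taken = taken, score = score, trajectory = trajectory)
}

#' Infer the activity of one pathway (condition-responsive genes)
#'
#' Member genes present in the matrix are z-scored, ordered by decreasing
#' absolute Welch t statistic between classes, and sign-aligned (genes with
#' negative t are negated). Genes are then greedily accumulated into the
#' CORG subset S while the absolute t of the running activity
#' `a_S = rowSums(z_S)/sqrt(|S|)` strictly increases; the search stops at
#' the first gene that fails to improve it. The combined activity is then
#' oriented to the majority direction of the selected genes, so a pathway
#' whose members are predominantly down-regulated in cases gets a lower
#' activity in cases (and discretizes to a `:down` item there).
#'
#' @param x an [OmicsMatrix-class].
#' @param geneSet character vector of member genes.
#' @return list with `activity` (named numeric over samples), `corg` (named
#'   numeric of +1/-1 signs, names = selected genes, in acceptance order)
#'   and `trajectory` (the strictly increasing |t| scores).
#' @export
inferPathwayActivity <- function(x, geneSet) {
  stopifnot(is(x, "OmicsMatrix"))
  labels <- sampleLabels(x)
  values <- omicsValues(x)
  members <- intersect(geneSet, rownames(values))
  if (!length(members)) stop("no member gene of the set is in the matrix")
  zs <- .zscoreRows(values[members, , drop = FALSE])
  isCase <- labels == "case"
  tvals <- apply(zs$z, 1L, function(r) tstatScore(r[isCase], r[!isCase]))
  ord <- order(-abs(tvals))
  signs <- ifelse(tvals[ord] < 0, -1, 1)
  zSigned <- zs$z[ord, , drop = FALSE] * signs
  fit <- .greedyCombine(zSigned, function(a)
    tstatScore(a[isCase], a[!isCase]))
  # orient the activity to the dominant original direction of the selected
  # genes, so a pathway whose members drop in cases gets a low case
  # activity (majority sign; ties resolved by the most discriminative gene)
  sel <- signs[fit$taken]
  orient <- sign(sum(sel))
  if (orient == 0) orient <- sel[1L]
  corg <- setNames(orient * sel, members[ord][fit$taken])
  list(activity = orient * fit$activity, corg = corg,
       trajectory = fit$trajectory)
}

#' Build a pathway activity profile
#'
#' Runs [inferPathwayActivity()] for every requested pathway.
#'
#' @param x an [OmicsMatrix-class].
#' @param gsc a [GeneSetCollection-class].
#' @param pathways pathway IDs to profile (default: all in `gsc` with at
#'   least one member gene in the matrix).
#' @return A [PathwayActivityProfile-class].
#' @export
pathwayActivityProfile <- function(x, gsc, pathways = NULL) {
  stopifnot(is(x, "OmicsMatrix"), is(gsc, "GeneSetCollection"))
  if (is.null(pathways)) {
    pathways <- names(gsc)[vapply(geneSets(gsc), function(g)
      any(g %in% rownames(x)), TRUE)]
  }
  missingSets <- setdiff(pathways, names(gsc))
  if (length(missingSets))
    stop("unknown pathway(s): ", paste(missingSets, collapse = ", "))
  fits <- lapply(pathways, function(p) inferPathwayActivity(x, gsc[[p]]))
  act <- do.call(rbind, lapply(fits, `[[`, "activity"))
  rownames(act) <- pathways
  new("PathwayActivityProfile",
      activities = act,
      corg = setNames(lapply(fits, `[[`, "corg"), pathways),
      labels = sampleLabels(x),
      datatype = dataType(x))
}

#' Discretize pathway activities to -1/+1 states
#'
#' Per pathway, a sample gets state +1 when its activity exceeds the
#' pathway's median activity across samples, and -1 otherwise (ties,
#' including constant rows, go down). The median split balances states and
#' is invariant to monotone transformations of each row.
#'
#' @param profile a [PathwayActivityProfile-class].
#' @return A [DiscretizedActivity-class].
#' @export
discretizeActivity <- function(profile) {
  stopifnot(is(profile, "PathwayActivityProfile"))
  act <- activityValues(profile)
  med <- apply(act, 1L, median)
  states <- ifelse(act > med, 1, -1)
  dimnames(states) <- dimnames(act)
  new("DiscretizedActivity", states = states, labels = sampleLabels(profile))
}

#' Encode -1/+1 states as a 2n-item binary transaction matrix
#'
#' An n-pathway state column `[+1, -1, +1]` becomes the 2n-bit column
#' `[1, 0, 1, 0, 1, 0]`: the first n bits flag up-regulation (or
#' hyper-methylation), the last n bits down-regulation (hypo-methylation).
#' Exactly one of a pathway's two bits is set in every sample.
#'
#' @param states a [DiscretizedActivity-class].
#' @return A [BinaryTransactionMatrix-class] with items named
#'   `"<pathway>:up"` and `"<pathway>:down"`.
#' @export
binarize <- function(states) {
  stopifnot(is(states, "DiscretizedActivity"))
  s <- activityStates(states)
  if (!all(s %in% c(-1, 1))) stop("states must be -1 or +1")
  up <- (s == 1) * 1L
  down <- (s == -1) * 1L
  rownames(up) <- paste0(rownames(s), ":up")
  rownames(down) <- paste0(rownames(s), ":down")
  new("BinaryTransactionMatrix", bits = rbind(up, down),
      pathways = rownames(s), labels = sampleLabels(states))
}

#' Decode a binary transaction matrix back to -1/+1 states
#'
#' Inverse of [binarize()].
#'
#' @param btm a [BinaryTransactionMatrix-class].
#' @return A [DiscretizedActivity-class].
#' @export
decodeBinary <- function(btm) {
  stopifnot(is(btm, "BinaryTransactionMatrix"))
  n <- length(pathwayNames(btm))
  up <- transactionBits(btm)[seq_len(n), , drop = FALSE]
  states <- ifelse(up == 1, 1, -1)
  rownames(states) <- pathwayNames(btm)
  new("DiscretizedActivity", states = states, labels = sampleLabels(btm))
}

#' Moderated two-sample t statistic (single feature)
#'
#' Pooled-variance two-sample t; with no prior information from other
#' features the empirical-Bayes prior weight is zero and the statistic
#' reduces exactly to the ordinary pooled t.
#'
#' @param values numeric vector over samples.
#' @param labels case/control factor named by sample (or in order).
#' @return the t statistic (case minus control).
#' @export
moderatedT <- function(values, labels) {
  labels <- .canonicalLabels(labels, names(values))
  a <- values[labels == "case"]
  b <- values[labels == "control"]
  if (length(a) < 2L || length(b) < 2L)
    stop("each class needs at least 2 samples")
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / max(sqrt(sp2 * (1 / length(a) + 1 / length(b))), 1e-12)
}

#' Moderated t statistics across features
#'
#' Feature-wise two-group t with empirical-Bayes variance shrinkage: pooled
#' per-feature variances are squeezed towards a common prior estimated
#' across features (`limma::squeezeVar`, i.e. `s2.post = (d0*s0^2 + d*s^2) /
#' (d0 + d)`). With fewer than `minFeatures` rows there is too little
#' information to estimate the prior and the prior weight is set to zero,
#' recovering the ordinary pooled t.
#'
#' @param values numeric matrix, features x samples.
#' @param labels case/control factor.
#' @param minFeatures minimum rows for prior estimation (default 30).
#' @return named numeric vector of moderated t statistics, with attributes
#'   `df.prior` and `s2.prior`.
#' @export
moderatedTStats <- function(values, labels, minFeatures = 30) {
  labels <- .canonicalLabels(labels, colnames(values))
  isCase <- labels == "case"
  n1 <- sum(isCase)
  n2 <- sum(!isCase)
  if (n1 < 2L || n2 < 2L) stop("each class needs at least 2 samples")
  m1 <- rowMeans(values[, isCase, drop = FALSE])
  m2 <- rowMeans(values[, !isCase, drop = FALSE])
  v1 <- apply(values[, isCase, drop = FALSE], 1L, var)
  v2 <- apply(values[, !isCase, drop = FALSE], 1L, var)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  df <- n1 + n2 - 2
  if (nrow(values) >= minFeatures) {
    sq <- limma::squeezeVar(s2, df = df)
    s2post <- sq$var.post
    d0 <- sq$df.prior
    s20 <- sq$var.prior
  } else {
    s2post <- s2
    d0 <- 0
    s20 <- NA_real_
  }
  tt <- (m1 - m2) / pmax(sqrt(s2post * (1 / n1 + 1 / n2)), 1e-12)
  names(tt) <- rownames(values)
  attr(tt, "df.prior") <- d0
  attr(tt, "s2.prior") <- s20
  tt
}

# Parse "P:up"/"P:down" item names into pathway + sign.
.parseItems <- function(items) {
  m <- regmatches(items, regexec("^(.*):(up|down)$", items))
  bad <- lengths(m) != 3L
  if (any(bad)) stop("malformed item name(s): ",
                     paste(items[bad], collapse = ", "))
  data.frame(pathway = vapply(m, `[[`, "", 2L),
             sign = ifelse(vapply(m, `[[`, "", 3L) == "up", 1, -1),
             stringsAsFactors = FALSE)
}

#' Combine a pathway-set into a single discriminative activity
#'
#' Applies the same greedy condition-responsive scheme as
#' [inferPathwayActivity()], but over pathway activity rows: rows are
#' z-scored, sign-aligned by the set's recorded up/down direction (a
#' down-annotated pathway contributes its negated activity), ordered by
#' decreasing absolute moderated t, and greedily accumulated while the
#' absolute moderated t of the combined activity strictly increases.
#'
#' @param profile a [PathwayActivityProfile-class].
#' @param itemset character vector of signed items, e.g.
#'   `c("P1:up", "P2:down")`.
#' @return list with `activity`, `selected` (signed items actually used),
#'   `model` (reusable projection: pathways, signs, centers, scales) and
#'   `trajectory`.
#' @export
pathwaySetActivity <- function(profile, itemset) {
  stopifnot(is(profile, "PathwayActivityProfile"))
  if (!length(itemset)) stop("empty pathway-set")
  parsed <- .parseItems(itemset)
  act <- activityValues(profile)
  missingP <- setdiff(parsed$pathway, rownames(act))
  if (length(missingP))
    stop("pathway(s) absent from the profile: ",
         paste(missingP, collapse = ", "))
  labels <- sampleLabels(profile)
  isCase <- labels == "case"
  zs <- .zscoreRows(act[parsed$pathway, , drop = FALSE])
  zSigned <- zs$z * parsed$sign
  tvals <- apply(zSigned, 1L, function(r)
    moderatedT(r, labels))
  ord <- order(-abs(tvals))
  fit <- .greedyCombine(zSigned[ord, , drop = FALSE], function(a)
    moderatedT(a, labels))
  sel <- ord[fit$taken]
  list(activity = fit$activity,
       selected = itemset[sel],
       model = list(pathways = parsed$pathway[sel],
                    signs = parsed$sign[sel],
                    centers = zs$center[sel],
                    scales = zs$scale[sel]),
       trajectory = fit$trajectory)
}

#' Project a fitted pathway-set activity model onto samples
#'
#' Applies the z-scoring parameters and signed combination learned by
#' [pathwaySetActivity()] (e.g. on training samples) to any activity
#' profile over the same pathways.
#'
#' @param model the `model` element returned by [pathwaySetActivity()].
#' @param activities pathway x sample activity matrix.
#' @return named numeric activity vector over the columns of `activities`.
#' @export
applyPathwaySetModel <- function(model, activities) {
  z <- (activities[model$pathways, , drop = FALSE] - model$centers) /
    model$scales
  colSums(z * model$signs) / sqrt(length(model$pathways))
}

#' Count pathways with inverse expression/methylation activity states
#'
#' A pathway is flagged inverse for a class when the majority discretized
#' state over that class's samples in the expression data is opposite to
#' the majority state in the methylation data. Each data type uses its own
#' sample set (the two matrices need not share samples); majority ties in
#' either data type mean "not inverse".
#'
#' @param exprStates,methStates [DiscretizedActivity-class] objects sharing
#'   pathway rows.
#' @param class `"case"` or `"control"`.
#' @return list with `nInverse` (count) and `flags` (named logical per
#'   shared pathway).
#' @export
inverseRelationshipCount <- function(exprStates, methStates,
                                     class = c("case", "control")) {
  class <- match.arg(class)
  shared <- intersect(rownames(activityStates(exprStates)),
                      rownames(activityStates(methStates)))
  if (!length(shared)) stop("no shared pathways between the two state sets")
  majority <- function(st) {
    cols <- sampleLabels(st) == class
    if (!any(cols)) stop("no ", class, " samples in one data type")
    s <- rowSums(activityStates(st)[shared, cols, drop = FALSE])
    sign(s)
  }
  mE <- majority(exprStates)
  mM <- majority(methStates)
  flags <- mE * mM == -1
  names(flags) <- shared
  list(nInverse = sum(flags), flags = flags)
}
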
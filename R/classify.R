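#' Sensitivity, specificity and accuracy from predictions
#'
#' Sensitivity = TP/(TP+FN) on the case class, specificity = TN/(TN+FP) on
#' the control class, accuracy = (TP+TN)/N, all reported in percent.
#'
#' @param predictions,truth case/control factors or characters of equal
#'   length.
#' @return named numeric: sensitivity, specificity, accuracy (percent).
#' @export
confusionMetrics <- function(predictions, truth) {
  pred <- factor(tolower(as.character(predictions)), levels = .CLASS_LEVELS)
  tr <- factor(tolower(as.character(truth)), levels = .CLASS_LEVELS)
  stopifnot(length(pred) == length(tr), !anyNA(pred), !anyNA(tr))
  tp <- sum(pred == "case" & tr == "case")
  fn <- sum(pred == "control" & tr == "case")
  tn <- sum(pred == "control" & tr == "control")
  fp <- sum(pred == "case" & tr == "control")
  c(sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    accuracy = 100 * (tp + tn) / length(tr))
}

# Train one classifier on (xtr, ytr) and predict xte. Settings follow
# common defaults: kNN k = 3 (Euclidean), linear SVM with C = 1, random
# forest with 500 trees, Gaussian naive Bayes.
.trainPredict <- function(classifier, xtr, ytr, xte) {
  switch(classifier,
    knn = class::knn(xtr, xte, ytr, k = 3),
    svm = {
      fit <- e1071::svm(xtr, ytr, kernel = "linear", cost = 1)
      stats::predict(fit, xte)
    },
    rf = {
      fit <- randomForest::randomForest(xtr, ytr, ntree = 500)
      stats::predict(fit, xte)
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(xtr, ytr)
      stats::predict(fit, as.data.frame(xte))
    },
    stop("unknown classifier: ", classifier)
  )
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin into nFolds folds.
.stratifiedFolds <- function(labels, nFolds) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < nFolds)
      stop("class ", cl, " has fewer samples than folds")
    fold[sample(idx)] <- rep_len(seq_len(nFolds), length(idx))
  }
  fold
}

#' Repeated stratified cross-validation of marker features
#'
#' Runs `nFolds`-fold stratified cross-validation repeated `nReps` times
#' (repetition r uses seed `seed + r - 1` for its partition; the default
#' seed 1 gives repetition seeds 1..8). Per repetition, test-fold
#' predictions are pooled over folds into one confusion matrix; the report
#' summarizes mean and sd of sensitivity, specificity and accuracy across
#' repetitions, in percent.
#'
#' Features can be a fixed samples-x-features matrix, or be rebuilt inside
#' each training fold by passing `featureBuilder`, a
#' `function(trainIdx, testIdx)` returning `list(train = , test = )`
#' matrices — this keeps fold-specific feature construction (e.g. refitting
#' pathway-set combinations) free of test-set information.
#'
#' @param features samples x features numeric matrix (rows named by
#'   sample), or NULL when `featureBuilder` is given.
#' @param labels case/control factor (named by sample or in row order).
#' @param classifiers subset of `c("knn", "svm", "rf", "naive_bayes")`.
#' @param nFolds folds (default 4).
#' @param nReps repetitions (default 8).
#' @param seed base seed (default 1).
#' @param featureBuilder optional fold-wise feature constructor (see
#'   Details).
#' @return A [ClassificationReport-class].
#' @export
crossValidate <- function(features, labels,
                          classifiers = c("knn", "svm", "rf", "naive_bayes"),
                          nFolds = 4, nReps = 8, seed = 1,
                          featureBuilder = NULL) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  if (!is.null(features)) {
    features <- as.matrix(features)
    labels <- .canonicalLabels(labels, rownames(features))
    nSamp <- nrow(features)
  } else {
    if (is.null(featureBuilder)) stop("need features or a featureBuilder")
    labels <- .canonicalLabels(labels)
    nSamp <- length(labels)
  }
  if (min(table(labels)) < nFolds)
    stop("each class needs at least nFolds samples")
  rows <- list()
  for (rep in seq_len(nReps)) {
    set.seed(seed + rep - 1L)
    fold <- .stratifiedFolds(labels, nFolds)
    pred <- setNames(vector("list", length(classifiers)), classifiers)
    truthAll <- factor(character(), levels = .CLASS_LEVELS)
    for (f in seq_len(nFolds)) {
      teIdx <- which(fold == f)
      trIdx <- which(fold != f)
      if (is.null(featureBuilder)) {
        xtr <- features[trIdx, , drop = FALSE]
        xte <- features[teIdx, , drop = FALSE]
      } else {
        built <- featureBuilder(trIdx, teIdx)
        xtr <- as.matrix(built$train)
        xte <- as.matrix(built$test)
      }
      truthAll <- c(truthAll, labels[teIdx])
      for (cl in classifiers) {
        p <- .trainPredict(cl, xtr, labels[trIdx], xte)
        pred[[cl]] <- c(pred[[cl]], as.character(p))
      }
    }
    for (cl in classifiers) {
      m <- confusionMetrics(pred[[cl]], truthAll)
      rows[[length(rows) + 1L]] <- data.frame(
        classifier = cl, rep = rep, sensitivity = m[["sensitivity"]],
        specificity = m[["specificity"]], accuracy = m[["accuracy"]],
        stringsAsFactors = FALSE)
    }
  }
  perRep <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(perRep, perRep$classifier), function(d)
    data.frame(classifier = d$classifier[1L],
               sensitivity.mean = mean(d$sensitivity),
               sensitivity.sd = sd(d$sensitivity),
               specificity.mean = mean(d$specificity),
               specificity.sd = sd(d$specificity),
               accuracy.mean = mean(d$accuracy),
               accuracy.sd = sd(d$accuracy),
               stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  new("ClassificationReport", perRep = perRep, summary = summ,
      settings = list(nFolds = nFolds, nReps = nReps, seed = seed,
                      classifiers = classifiers,
                      knn.k = 3, svm.kernel = "linear", svm.cost = 1,
                      rf.ntree = 500, nb = "gaussian"))
}

#' Per-repetition accuracies of one classifier
#'
#' @param report a [ClassificationReport-class].
#' @param classifier classifier name.
#' @return numeric vector of accuracies (percent), in repetition order.
#' @export
repAccuracies <- function(report, classifier) {
  d <- report@perRep[report@perRep$classifier == classifier, ]
  d$accuracy[order(d$rep)]
}

#' Paired t-test between two accuracy series
#'
#' Two-sided paired t-test over matched repetition accuracies. When the
#' paired differences have zero variance (including identical vectors) the
#' statistic is undefined and NaN is returned with a warning.
#'
#' @param accA,accB equal-length (>= 2) numeric vectors of per-repetition
#'   accuracies.
#' @return the p-value, or NaN for degenerate differences.
#' @export
pairedTTestAccuracies <- function(accA, accB) {
  if (length(accA) != length(accB) || length(accA) < 2L)
    stop("need two equal-length accuracy vectors of length >= 2")
  d <- accA - accB
  if (sd(d) == 0) {
    warning("paired differences have zero variance; p-value undefined (NaN)")
    return(NaN)
  }
  t.test(accA, accB, paired = TRUE)$p.value
}

#' Build a samples-x-features marker matrix
#'
#' `"genes"`: expression rows of the marker genes; `"pathways"`: pathway
#' activity rows; `"pathway_sets"`: one feature per marker, the combined
#' activity from [pathwaySetActivity()] fitted on all samples (for
#' leak-free cross-validation use [pathwaySetFeatureBuilder()] instead).
#'
#' @param markerType `"genes"`, `"pathways"` or `"pathway_sets"`.
#' @param markers gene symbols / pathway IDs, or the marker data.frame from
#'   [rankAndSelect()] for pathway-sets.
#' @param profile a [PathwayActivityProfile-class] (pathway-based types).
#' @param x an [OmicsMatrix-class] (gene markers).
#' @return numeric matrix, samples x features.
#' @export
buildFeatureMatrix <- function(markerType = c("genes", "pathways",
                                              "pathway_sets"),
                               markers, profile = NULL, x = NULL) {
  markerType <- match.arg(markerType)
  if (markerType == "genes") {
    stopifnot(is(x, "OmicsMatrix"))
    missingG <- setdiff(markers, rownames(x))
    if (length(missingG))
      stop("unknown gene marker(s): ", paste(missingG, collapse = ", "))
    return(t(omicsValues(x)[markers, , drop = FALSE]))
  }
  stopifnot(is(profile, "PathwayActivityProfile"))
  if (markerType == "pathways") {
    missingP <- setdiff(markers, rownames(activityValues(profile)))
    if (length(missingP))
      stop("unknown pathway marker(s): ", paste(missingP, collapse = ", "))
    return(t(activityValues(profile)[markers, , drop = FALSE]))
  }
  stopifnot(is.data.frame(markers), "items" %in% colnames(markers))
  feats <- vapply(markers$items, function(its)
    pathwaySetActivity(profile, its)$activity,
    numeric(ncol(activityValues(profile))))
  colnames(feats) <- paste0(markers$class, ".", markers$rank)
  feats
}

#' Fold-wise pathway-set feature builder for cross-validation
#'
#' Returns a `featureBuilder` for [crossValidate()] that refits each
#' marker's pathway combination ([pathwaySetActivity()]) on the training
#' samples only and projects the fitted model onto the test samples, so no
#' test-fold information enters feature construction.
#'
#' @param profile a [PathwayActivityProfile-class] over all samples.
#' @param markers marker data.frame from [rankAndSelect()].
#' @return `function(trainIdx, testIdx)` usable as `featureBuilder`.
#' @export
pathwaySetFeatureBuilder <- function(profile, markers) {
  act <- activityValues(profile)
  labels <- sampleLabels(profile)
  function(trainIdx, testIdx) {
    trProfile <- new("PathwayActivityProfile",
                     activities = act[, trainIdx, drop = FALSE],
                     corg = profile@corg, labels = labels[trainIdx],
                     datatype = profile@datatype)
    tr <- matrix(0, length(trainIdx), nrow(markers))
    te <- matrix(0, length(testIdx), nrow(markers))
    for (i in seq_len(nrow(markers))) {
      fit <- pathwaySetActivity(trProfile, markers$items[[i]])
      tr[, i] <- fit$activity
      te[, i] <- applyPathwaySetModel(fit$model,
                                      act[, testIdx, drop = FALSE])
    }
    list(train = tr, test = te)
  }
}
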
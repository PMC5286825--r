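#' Accessors for panminer classes
#'
#' `omicsValues` returns the numeric gene-by-sample matrix, `sampleLabels`
#' the named case/control factor, `dataType` the expression/methylation tag,
#' `activityValues` the pathway-by-sample activity matrix, `corgGenes` the
#' signed condition-responsive gene subsets, `activityStates` the -1/+1 state
#' matrix, `transactionBits` the 2n-item 0/1 matrix, `pathwayNames` the
#' pathway IDs behind a transaction matrix, and `geneSets` the member-gene
#' list of a collection.
#'
#' @param x a panminer object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("omicsValues", function(x) standardGeneric("omicsValues"))

#' @rdname accessors
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname accessors
#' @export
setGeneric("dataType", function(x) standardGeneric("dataType"))

#' @rdname accessors
#' @export
setGeneric("activityValues", function(x) standardGeneric("activityValues"))

#' @rdname accessors
#' @export
setGeneric("corgGenes", function(x) standardGeneric("corgGenes"))

#' @rdname accessors
#' @export
setGeneric("activityStates", function(x) standardGeneric("activityStates"))

#' @rdname accessors
#' @export
setGeneric("transactionBits", function(x) standardGeneric("transactionBits"))

#' @rdname accessors
#' @export
setGeneric("pathwayNames", function(x) standardGeneric("pathwayNames"))

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setMethod("omicsValues", "OmicsMatrix", function(x)
  SummarizedExperiment::assay(x, "values"))

#' @rdname accessors
#' @export
setMethod("sampleLabels", "OmicsMatrix", function(x)
  setNames(SummarizedExperiment::colData(x)$class, colnames(x)))

#' @rdname accessors
#' @export
setMethod("dataType", "OmicsMatrix", function(x) x@datatype)

#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname accessors
#' @export
setMethod("dataType", "PathwayActivityProfile", function(x) x@datatype)

#' @rdname accessors
#' @export
setMethod("sampleLabels", "PathwayActivityProfile", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("activityValues", "PathwayActivityProfile", function(x) x@activities)

#' @rdname accessors
#' @export
setMethod("corgGenes", "PathwayActivityProfile", function(x) x@corg)

#' @rdname accessors
#' @export
setMethod("sampleLabels", "DiscretizedActivity", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("activityStates", "DiscretizedActivity", function(x) x@states)

#' @rdname accessors
#' @export
setMethod("sampleLabels", "BinaryTransactionMatrix", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("transactionBits", "BinaryTransactionMatrix", function(x) x@bits)

#' @rdname accessors
#' @export
setMethod("pathwayNames", "BinaryTransactionMatrix", function(x) x@pathways)

#' @describeIn GeneSetCollection-class number of gene sets.
#' @param x a `GeneSetCollection`.
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @describeIn GeneSetCollection-class set IDs.
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @describeIn GeneSetCollection-class member genes of one set.
#' @param i set ID or index.
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

setMethod("show", "OmicsMatrix", function(object) {
  lab <- sampleLabels(object)
  cat("OmicsMatrix (", object@datatype, "): ",
      nrow(object), " features x ", ncol(object), " samples (",
      sum(lab == "case"), " case / ", sum(lab == "control"), " control)\n",
      sep = "")
})

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection:", length(object@sets), "sets, sizes",
      if (length(object@sets)) paste0(min(lengths(object@sets)), "-",
                                      max(lengths(object@sets))) else "-",
      "\n")
})

setMethod("show", "PathwayActivityProfile", function(object) {
  cat("PathwayActivityProfile (", object@datatype, "): ",
      nrow(object@activities), " pathways x ", ncol(object@activities),
      " samples\n", sep = "")
})

setMethod("show", "DiscretizedActivity", function(object) {
  cat("DiscretizedActivity:", nrow(object@states), "pathways x",
      ncol(object@states), "samples\n")
})

setMethod("show", "BinaryTransactionMatrix", function(object) {
  cat("BinaryTransactionMatrix:", nrow(object@bits), "items (",
      length(object@pathways), "pathways ) x", ncol(object@bits),
      "samples\n")
})

setMethod("show", "PAN", function(object) {
  cat("PAN [", object@className, "]: ", nrow(object@nodes), " nodes, ",
      nrow(object@edges), " edges\n", sep = "")
})

setMethod("show", "ClassificationReport", function(object) {
  cat("ClassificationReport:", object@settings$nFolds, "folds x",
      object@settings$nReps, "repetitions\n")
  print(object@summary, row.names = FALSE)
})
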
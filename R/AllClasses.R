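#' @import methods
#' @importFrom stats median p.adjust rnorm sd t.test var setNames rbinom
#' @importFrom utils combn head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.CLASS_LEVELS <- c("case", "control")

# Coerce user-supplied labels (character/factor, named by sample) to the
# canonical case/control factor, matched case-insensitively.
.canonicalLabels <- function(labels, sampleIDs = NULL) {
  if (is.null(names(labels)) && !is.null(sampleIDs) &&
      length(labels) == length(sampleIDs)) {
    names(labels) <- sampleIDs
  }
  lab <- tolower(as.character(labels))
  bad <- !lab %in% .CLASS_LEVELS
  if (any(bad)) {
    stop("labels must be 'case' or 'control' (case-insensitive); offending: ",
         paste(unique(lab[bad]), collapse = ", "))
  }
  out <- factor(lab, levels = .CLASS_LEVELS)
  names(out) <- names(labels)
  if (!is.null(sampleIDs)) {
    if (!all(sampleIDs %in% names(out))) {
      stop("every sample ID needs a label; missing: ",
           paste(setdiff(sampleIDs, names(out)), collapse = ", "))
    }
    out <- out[sampleIDs]
  }
  out
}

#' OmicsMatrix: a labelled gene-by-sample matrix
#'
#' Container for a numeric gene (or probe) by sample matrix together with a
#' binary case/control sample labelling and a data-type tag (expression or
#' methylation). Extends
#' [SummarizedExperiment::SummarizedExperiment-class]; the values live in the
#' single assay `"values"` and the labels in `colData(x)$class`.
#'
#' @slot datatype `"expression"` or `"methylation"`.
#' @export
setClass("OmicsMatrix",
  contains = "SummarizedExperiment",
  representation(datatype = "character")
)

setValidity("OmicsMatrix", function(object) {
  msg <- character()
  if (!object@datatype %in% c("expression", "methylation"))
    msg <- c(msg, "datatype must be 'expression' or 'methylation'")
  v <- SummarizedExperiment::assay(object)
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (anyNA(v)) msg <- c(msg, "missing values are not allowed")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msg <- c(msg, "row identifiers must be present and unique")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msg <- c(msg, "sample identifiers must be present and unique")
  cd <- SummarizedExperiment::colData(object)
  if (!"class" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain a 'class' column")
  } else {
    cl <- cd$class
    if (!all(levels(cl) == .CLASS_LEVELS) || anyNA(cl))
      msg <- c(msg, "class labels must be a case/control factor without NA")
    else if (any(table(cl) == 0))
      msg <- c(msg, "both classes must be non-empty")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsMatrix
#'
#' @param values numeric matrix, rows = genes/probes, columns = samples; row
#'   and column names required.
#' @param labels character or factor of `"case"`/`"control"` (matched
#'   case-insensitively), named by sample ID or given in column order.
#' @param datatype `"expression"` (default) or `"methylation"`.
#' @return An [OmicsMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("G", 1:4), paste0("S", 1:5)))
#' om <- OmicsMatrix(m, c("case", "case", "case", "control", "control"))
#' @export
OmicsMatrix <- function(values, labels,
                        datatype = c("expression", "methylation")) {
  datatype <- match.arg(datatype)
  values <- as.matrix(values)
  lab <- .canonicalLabels(labels, colnames(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = values),
    colData = S4Vectors::DataFrame(class = unname(lab),
                                   row.names = colnames(values))
  )
  new("OmicsMatrix", se, datatype = datatype)
}

#' GeneSetCollection: a named collection of gene sets
#'
#' Holds a pathway-ID-keyed list of member gene symbols (unique within a set)
#' plus one description per set, as parsed from a GMT file.
#'
#' @slot sets named list of character vectors (member genes, duplicates
#'   removed preserving first occurrence).
#' @slot descriptions named character vector, same names as `sets`.
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", descriptions = "character")
)

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msg <- c(msg, "set IDs must be present and unique")
  if (any(lengths(object@sets) == 0))
    msg <- c(msg, "empty gene sets are not allowed")
  if (any(vapply(object@sets, anyDuplicated, 0L) > 0))
    msg <- c(msg, "gene symbols within a set must be unique")
  if (length(object@descriptions) != length(object@sets) ||
      !identical(names(object@descriptions), names(object@sets)))
    msg <- c(msg, "descriptions must parallel sets")
  if (length(msg)) msg else TRUE
})

#' @rdname GeneSetCollection-class
#' @param sets named list of character vectors of gene symbols.
#' @param descriptions optional named character vector of set descriptions.
#' @export
GeneSetCollection <- function(sets, descriptions = NULL) {
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("", length(sets)), names(sets))
  }
  new("GeneSetCollection", sets = sets,
      descriptions = descriptions[names(sets)])
}

#' PathwayActivityProfile: continuous pathway-by-sample activities
#'
#' @slot activities numeric matrix, rows = pathways, columns = samples.
#' @slot corg named list giving, per pathway, the signed condition-responsive
#'   gene subset the activity was built from (names = genes, values = +1/-1
#'   sign applied to the gene's z-scores).
#' @slot labels case/control factor named by sample.
#' @slot datatype `"expression"` or `"methylation"`.
#' @export
setClass("PathwayActivityProfile",
  representation(activities = "matrix", corg = "list",
                 labels = "factor", datatype = "character")
)

setValidity("PathwayActivityProfile", function(object) {
  msg <- character()
  if (!identical(names(object@corg), rownames(object@activities)))
    msg <- c(msg, "corg entries must parallel activity rows")
  if (any(lengths(object@corg) < 1))
    msg <- c(msg, "every pathway needs at least one CORG gene")
  if (!identical(names(object@labels), colnames(object@activities)))
    msg <- c(msg, "labels must be named by the activity columns")
  if (length(msg)) msg else TRUE
})

#' DiscretizedActivity: per-sample up/down pathway states
#'
#' @slot states matrix over \{-1, +1\}, rows = pathways, columns = samples.
#' @slot labels case/control factor named by sample.
#' @export
setClass("DiscretizedActivity",
  representation(states = "matrix", labels = "factor")
)

setValidity("DiscretizedActivity", function(object) {
  msg <- character()
  if (!all(object@states %in% c(-1, 1)))
    msg <- c(msg, "states must be -1 or +1")
  if (!identical(names(object@labels), colnames(object@states)))
    msg <- c(msg, "labels must be named by the state columns")
  if (length(msg)) msg else TRUE
})

#' BinaryTransactionMatrix: 2n-item up/down encoding of pathway states
#'
#' Each of the n pathways contributes two items, `"<pathway>:up"` (rows
#' 1..n) and `"<pathway>:down"` (rows n+1..2n); for every pathway and sample
#' exactly one of the two bits is set.
#'
#' @slot bits 0/1 matrix, rows = 2n items, columns = samples.
#' @slot pathways the n pathway IDs in row order.
#' @slot labels case/control factor named by sample.
#' @export
setClass("BinaryTransactionMatrix",
  representation(bits = "matrix", pathways = "character", labels = "factor")
)

setValidity("BinaryTransactionMatrix", function(object) {
  msg <- character()
  n <- length(object@pathways)
  b <- object@bits
  if (nrow(b) != 2L * n)
    msg <- c(msg, "bits must have 2n rows")
  if (!all(b %in% c(0, 1)))
    msg <- c(msg, "bits must be 0/1")
  else if (n > 0 && !all(b[seq_len(n), , drop = FALSE] +
                         b[n + seq_len(n), , drop = FALSE] == 1))
    msg <- c(msg, "exactly one of up/down must be set per pathway and sample")
  if (!identical(names(object@labels), colnames(b)))
    msg <- c(msg, "labels must be named by the bit columns")
  if (length(msg)) msg else TRUE
})

#' PAN: a per-class pathway activity network
#'
#' Nodes are pathways appearing in at least one pathway-set marker of the
#' class, sized by -log2 of the p-value of the class difference of their
#' activity and coloured by majority activity direction; edges connect
#' pathways co-occurring in markers, weighted by the fraction of the class's
#' markers containing both endpoints.
#'
#' @slot class `"case"` or `"control"`.
#' @slot nodes data.frame with columns pathway, significance, direction,
#'   p.value.
#' @slot edges data.frame with columns from, to, count, weight.
#' @export
setClass("PAN",
  representation(className = "character", nodes = "data.frame",
                 edges = "data.frame")
)

setValidity("PAN", function(object) {
  msg <- character()
  if (!object@className %in% .CLASS_LEVELS)
    msg <- c(msg, "class must be 'case' or 'control'")
  need <- c("pathway", "significance", "direction", "p.value")
  if (!all(need %in% colnames(object@nodes)))
    msg <- c(msg, "nodes need columns pathway/significance/direction/p.value")
  needE <- c("from", "to", "count", "weight")
  if (!all(needE %in% colnames(object@edges)))
    msg <- c(msg, "edges need columns from/to/count/weight")
  if (nrow(object@edges) &&
      !all(c(object@edges$from, object@edges$to) %in% object@nodes$pathway))
    msg <- c(msg, "every edge endpoint must be a node")
  if (nrow(object@edges) &&
      (any(object@edges$weight <= 0) || any(object@edges$weight > 1)))
    msg <- c(msg, "edge weights must lie in (0, 1]")
  if (nrow(object@nodes) && any(object@nodes$significance < 0))
    msg <- c(msg, "node significance must be non-negative")
  if (length(msg)) msg else TRUE
})

#' ClassificationReport: repeated cross-validation results
#'
#' @slot perRep data.frame with one row per classifier x repetition holding
#'   pooled sensitivity, specificity and accuracy (percent).
#' @slot summary data.frame with per-classifier mean and sd (percent).
#' @slot settings list recording classifier settings, fold/repetition counts
#'   and the seed.
#' @export
setClass("ClassificationReport",
  representation(perRep = "data.frame", summary = "data.frame",
                 settings = "list")
)
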
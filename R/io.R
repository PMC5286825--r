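#' Read a GMT gene-set file
#'
#' One set per line: `name <tab> description <tab> gene1 <tab> gene2 ...`.
#' Duplicate gene symbols within a line are removed preserving first
#' occurrence; empty gene fields (trailing tabs) are dropped.
#'
#' @param path path to a GMT file.
#' @return A [GeneSetCollection-class].
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(GeneSetCollection(structure(list(), names = character())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed GMT line (fewer than 3 fields) at line ",
         which(nf < 3)[1])
  }
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate pathway ID in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sets <- lapply(fields, function(f) {
    g <- f[-c(1L, 2L)]
    unique(g[nzchar(g)])
  })
  names(sets) <- ids
  desc <- setNames(vapply(fields, `[[`, "", 2L), ids)
  GeneSetCollection(sets, desc)
}

#' Write a GeneSetCollection to GMT
#'
#' @param gsc a [GeneSetCollection-class].
#' @param path output path.
#' @export
writeGMT <- function(gsc, path) {
  lines <- vapply(names(gsc), function(id) {
    paste(c(id, gsc@descriptions[[id]], gsc[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene/probe-by-sample matrix (TSV or GCT 1.2)
#'
#' Plain TSV: a header row of sample IDs and a first column of row IDs.
#' GCT 1.2 (detected by a first line starting with `#1.2`): the two header
#' lines are skipped and the Description column dropped. Missing values are
#' an error, not imputed.
#'
#' @param path path to the matrix file.
#' @return numeric matrix with row and column names.
#' @export
readMatrixFile <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  first <- readLines(path, n = 1L)
  skip <- if (startsWith(first, "#1.2")) 2L else 0L
  df <- utils::read.delim(path, skip = skip, check.names = FALSE,
                          stringsAsFactors = FALSE)
  idcol <- 1L
  drop <- idcol
  if (skip == 2L && ncol(df) >= 2L &&
      tolower(colnames(df)[2L]) == "description") {
    drop <- c(drop, 2L)
  }
  m <- as.matrix(df[, -drop, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[idcol]])
  if (anyNA(m)) stop("matrix contains missing values; imputation is not supported")
  m
}

#' Read a two-column sample-label TSV
#'
#' First column sample ID, second column label (`case`/`control`,
#' case-insensitive). A header line is tolerated if its second field does not
#' parse as a label.
#'
#' @param path path to the labels file.
#' @return named case/control factor.
#' @export
readLabels <- function(path) {
  if (!file.exists(path)) stop("labels file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("labels file needs two columns: sample ID, label")
  if (!tolower(df[1, 2]) %in% .CLASS_LEVELS) df <- df[-1, , drop = FALSE]
  .canonicalLabels(setNames(df[[2]], df[[1]]))
}

#' Write an OmicsMatrix (or plain matrix) as TSV
#'
#' Values are written at full precision (`format(..., digits = 17)` via
#' write.table default formatting of doubles).
#'
#' @param x an [OmicsMatrix-class] or numeric matrix.
#' @param path output path.
#' @param idColumn name of the leading identifier column.
#' @export
writeMatrixFile <- function(x, path, idColumn = "id") {
  m <- if (is(x, "OmicsMatrix")) omicsValues(x) else x
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- idColumn
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse probe rows to gene rows by averaging
#'
#' Probes mapping to the same gene symbol are replaced by their per-sample
#' arithmetic mean; probes absent from the map are dropped (count reported
#' via a message).
#'
#' @param probeMatrix numeric matrix keyed by probe ID.
#' @param probeMap named character vector, probe ID -> gene symbol.
#' @param labels sample labels (see [OmicsMatrix()]).
#' @param datatype `"expression"` or `"methylation"`.
#' @return An [OmicsMatrix-class] keyed by gene symbol.
#' @export
collapseProbes <- function(probeMatrix, probeMap, labels,
                           datatype = c("expression", "methylation")) {
  datatype <- match.arg(datatype)
  if (!length(probeMap)) stop("probeMap is empty")
  probeMatrix <- as.matrix(probeMatrix)
  mapped <- rownames(probeMatrix) %in% names(probeMap)
  if (any(!mapped)) {
    message(sum(!mapped), " probe(s) without gene mapping dropped")
  }
  m <- probeMatrix[mapped, , drop = FALSE]
  if (!nrow(m)) stop("no probes left after mapping")
  genes <- unname(probeMap[rownames(m)])
  # rowsum sums per gene; divide by probe multiplicity for the mean
  sums <- rowsum(m, genes)
  counts <- as.vector(table(genes)[rownames(sums)])
  OmicsMatrix(sums / counts, labels, datatype)
}

#' Remove low-variance rows
#'
#' Rows whose sample variance falls below `threshold` are removed; the order
#' of surviving rows is preserved. `threshold = 0` disables the filter.
#'
#' @param x an [OmicsMatrix-class].
#' @param threshold non-negative variance cutoff.
#' @return filtered [OmicsMatrix-class].
#' @export
varianceFilter <- function(x, threshold = 0) {
  stopifnot(is(x, "OmicsMatrix"))
  if (threshold < 0) stop("threshold must be non-negative")
  if (threshold == 0) return(x)
  v <- omicsValues(x)
  rv <- apply(v, 1L, var)
  keep <- rv >= threshold
  if (!any(keep)) {
    stop("variance filter removed every row; lower the threshold (",
         threshold, ")")
  }
  x[keep, ]
}

#' Z-score rows (zero-mean, unit-variance normalization)
#'
#' Each row is centred to mean zero and scaled to unit sample standard
#' deviation, putting genes measured on different scales onto a common one.
#' Zero-variance rows cannot be scaled and are an error; filter them out
#' first with [varianceFilter()].
#'
#' @param x an [OmicsMatrix-class] with at least two samples.
#' @return normalized [OmicsMatrix-class].
#' @export
zeroMeanNormalize <- function(x) {
  stopifnot(is(x, "OmicsMatrix"))
  v <- omicsValues(x)
  if (ncol(v) < 2L) stop("need at least 2 samples to normalize")
  mu <- rowMeans(v)
  s <- apply(v, 1L, sd)
  if (any(s == 0)) {
    stop("zero-variance row(s) cannot be z-scored: ",
         paste(head(rownames(v)[s == 0], 5L), collapse = ", "),
         "; apply varianceFilter() first")
  }
  z <- (v - mu) / s
  SummarizedExperiment::assay(x, "values") <- z
  x
}

#' Full preprocessing pipeline
#'
#' Convenience wrapper running probe collapsing (optional), variance
#' filtering and z-score normalization in the required order.
#'
#' @inheritParams collapseProbes
#' @inheritParams varianceFilter
#' @return normalized [OmicsMatrix-class].
#' @export
prepareOmicsMatrix <- function(probeMatrix, labels, probeMap = NULL,
                               threshold = 0,
                               datatype = c("expression", "methylation")) {
  datatype <- match.arg(datatype)
  om <- if (is.null(probeMap)) {
    OmicsMatrix(probeMatrix, labels, datatype)
  } else {
    collapseProbes(probeMatrix, probeMap, labels, datatype)
  }
  zeroMeanNormalize(varianceFilter(om, threshold))
}
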
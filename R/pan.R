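#' Node significance: -log2 of the class-difference p-value
#'
#' The p-value is from a Welch two-sample t-test on a pathway's continuous
#' activity between classes; the node size in a PAN is `-log2(p)` with p
#' floored at 1e-300.
#'
#' @param activityRow named numeric activity over samples.
#' @param labels case/control factor named by sample.
#' @return list with `significance` and `p.value`.
#' @export
nodeSignificance <- function(activityRow, labels) {
  labels <- .canonicalLabels(labels, names(activityRow))
  a <- activityRow[labels == "case"]
  b <- activityRow[labels == "control"]
  if (length(a) < 2L || length(b) < 2L)
    stop("each class needs at least 2 samples")
  p <- t.test(a, b)$p.value
  p <- max(p, 1e-300)
  list(significance = -log2(p), p.value = p)
}

#' Edge co-occurrence frequencies across markers
#'
#' For each unordered pathway pair (item directions ignored), counts the
#' markers whose itemsets contain both pathways; the edge weight is that
#' count divided by the total number of markers supplied. Pairs never
#' co-occurring are omitted.
#'
#' @param markerItemsets list of character itemsets (signed items).
#' @return data.frame with columns from, to, count, weight.
#' @export
edgeFrequencies <- function(markerItemsets) {
  if (!length(markerItemsets)) stop("need at least one marker")
  total <- length(markerItemsets)
  tallies <- new.env(parent = emptyenv())
  for (its in markerItemsets) {
    pw <- sort(.itemPathways(its))
    if (length(pw) < 2L) next
    prs <- combn(pw, 2L)
    for (j in seq_len(ncol(prs))) {
      key <- paste(prs[1L, j], prs[2L, j], sep = "\r")
      tallies[[key]] <- (if (is.null(tallies[[key]])) 0L
                         else tallies[[key]]) + 1L
    }
  }
  keys <- sort(ls(tallies))
  if (!length(keys)) {
    return(data.frame(from = character(), to = character(),
                      count = integer(), weight = numeric(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(keys, "\r", fixed = TRUE)
  counts <- vapply(keys, function(k) tallies[[k]], 0L)
  data.frame(from = vapply(parts, `[[`, "", 1L),
             to = vapply(parts, `[[`, "", 2L),
             count = unname(counts), weight = unname(counts) / total,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build a per-class pathway activity network
#'
#' Nodes are the pathways appearing in at least one of the class's markers;
#' each node carries `-log2(p)` significance (Welch t on its continuous
#' activity between classes, via [nodeSignificance()]) and a direction: up
#' when the majority of the class's samples have discretized state +1, down
#' otherwise (ties go down). Edges come from [edgeFrequencies()] over the
#' class's marker itemsets.
#'
#' @param markers marker data.frame from [rankAndSelect()].
#' @param profile a [PathwayActivityProfile-class].
#' @param states the matching [DiscretizedActivity-class].
#' @param class `"case"` or `"control"`.
#' @return A [PAN-class].
#' @export
buildPAN <- function(markers, profile, states, class = c("case", "control")) {
  class <- match.arg(class)
  stopifnot(is(profile, "PathwayActivityProfile"),
            is(states, "DiscretizedActivity"))
  mk <- markers[markers$class == class, , drop = FALSE]
  if (!nrow(mk)) stop("no markers for class ", class)
  pathways <- sort(unique(unlist(lapply(mk$items, .itemPathways))))
  missingP <- setdiff(pathways, rownames(activityValues(profile)))
  if (length(missingP))
    stop("activities missing for pathway(s): ",
         paste(missingP, collapse = ", "))
  labels <- sampleLabels(profile)
  sig <- lapply(pathways, function(p)
    nodeSignificance(activityValues(profile)[p, ], labels))
  st <- activityStates(states)
  inClass <- sampleLabels(states) == class
  direction <- vapply(pathways, function(p) {
    if (sum(st[p, inClass]) > 0) "up" else "down"
  }, "")
  nodes <- data.frame(pathway = pathways,
                      significance = vapply(sig, `[[`, 0, "significance"),
                      direction = unname(direction),
                      p.value = vapply(sig, `[[`, 0, "p.value"),
                      row.names = NULL, stringsAsFactors = FALSE)
  new("PAN", className = class, nodes = nodes,
      edges = edgeFrequencies(mk$items))
}

#' Weighted node degrees of a PAN
#'
#' @param pan a [PAN-class].
#' @return named numeric: sum of incident edge weights per node.
#' @export
panDegree <- function(pan) {
  deg <- setNames(numeric(nrow(pan@nodes)), pan@nodes$pathway)
  if (nrow(pan@edges)) {
    for (i in seq_len(nrow(pan@edges))) {
      deg[pan@edges$from[i]] <- deg[pan@edges$from[i]] + pan@edges$weight[i]
      deg[pan@edges$to[i]] <- deg[pan@edges$to[i]] + pan@edges$weight[i]
    }
  }
  deg
}

#' Convert a PAN to an igraph graph
#'
#' @param pan a [PAN-class].
#' @return an undirected [igraph::igraph] with vertex attributes
#'   significance, direction, p.value and edge attributes weight, count.
#' @export
panToIgraph <- function(pan) {
  g <- igraph::graph_from_data_frame(
    if (nrow(pan@edges)) pan@edges else
      data.frame(from = character(), to = character()),
    directed = FALSE, vertices = pan@nodes)
  igraph::graph_attr(g, "class") <- pan@className
  g
}

#' Export a PAN to GraphML, SIF or JSON
#'
#' GraphML (via igraph) and JSON are lossless for node/edge sets and
#' attributes; SIF writes `from assoc to` lines plus an `<out>.attrs.tsv`
#' sidecar with edge weights and counts.
#'
#' @param pan a [PAN-class].
#' @param path output path.
#' @param format `"graphml"`, `"sif"` or `"json"`.
#' @return the path, invisibly.
#' @export
exportPAN <- function(pan, path, format = c("graphml", "sif", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(panToIgraph(pan), path, format = "graphml")
  } else if (format == "json") {
    jsonlite::write_json(list(class = pan@className, nodes = pan@nodes,
                              edges = pan@edges),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    lines <- if (nrow(pan@edges)) {
      paste(pan@edges$from, "assoc", pan@edges$to)
    } else character()
    iso <- setdiff(pan@nodes$pathway,
                   c(pan@edges$from, pan@edges$to))
    writeLines(c(lines, iso), path)
    utils::write.table(
      cbind(pan@edges[, c("from", "to", "weight", "count")]),
      paste0(path, ".attrs.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  invisible(path)
}

#' Re-import a PAN written by exportPAN
#'
#' Supports the `"graphml"` and `"json"` formats.
#'
#' @param path file path.
#' @param format `"graphml"` or `"json"`.
#' @return A [PAN-class].
#' @export
importPAN <- function(path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    nodes <- as.data.frame(obj$nodes, stringsAsFactors = FALSE)
    edges <- if (length(obj$edges)) {
      as.data.frame(obj$edges, stringsAsFactors = FALSE)
    } else {
      data.frame(from = character(), to = character(), count = integer(),
                 weight = numeric(), stringsAsFactors = FALSE)
    }
    return(new("PAN", className = obj$class, nodes = nodes, edges = edges))
  }
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(
    pathway = igraph::V(g)$name,
    significance = igraph::V(g)$significance,
    direction = igraph::V(g)$direction,
    p.value = igraph::V(g)$p.value,
    stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  edges <- if (nrow(el)) {
    data.frame(from = el[, 1L], to = el[, 2L],
               count = igraph::E(g)$count,
               weight = igraph::E(g)$weight, stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(), to = character(), count = integer(),
               weight = numeric(), stringsAsFactors = FALSE)
  }
  ord <- order(nodes$pathway)
  new("PAN", className = igraph::graph_attr(g, "class"),
      nodes = nodes[ord, , drop = FALSE], edges = edges)
}
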
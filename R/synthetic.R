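#' Configuration for the synthetic omics generator
#'
#' Defaults emulate a two-class microarray study of moderate size: 40 case
#' and 40 control samples, 40 pathways of 25-100 member genes each (drawn
#' disjoint) plus unassigned background genes, standard-normal noise, and
#' differential signal in standard-deviation units (`delta = 2`). Signal
#' comes in two forms: *active pathways*, whose member genes are shifted by
#' `delta` in every sample of their class, and *planted pathway-sets*,
#' groups of direction-annotated pathways co-activated in the same samples
#' via a per-sample Bernoulli "module on" indicator (probability
#' `penetrance` in the set's class, `leak` in the other class) — the ground
#' truth the rule-mining stage should recover. An optional methylation
#' mirror applies every shift with flipped sign to a second matrix,
#' emulating the inverse expression/methylation relationship.
#'
#' @param nCase,nControl samples per class.
#' @param nPathways number of pathways in the collection.
#' @param pathwaySizeRange inclusive range of member-gene counts.
#' @param nBackgroundGenes unassigned noise genes.
#' @param delta effect size, in units of the noise sd.
#' @param nActiveCase,nActiveControl number of class-wide active pathways
#'   per class (up-shifted in that class's samples).
#' @param plantedSets list of planted pathway-sets, each a list with
#'   `items` (signed, e.g. `c("PW01:up","PW03:down")`), `class`,
#'   `penetrance`, `leak`.
#' @param noiseSd noise standard deviation.
#' @param methylationMirror logical; also generate a sign-flipped
#'   methylation matrix.
#' @param seed integer seed.
#' @return validated config list (class `"syntheticConfig"`).
#' @export
syntheticConfig <- function(nCase = 40, nControl = 40, nPathways = 40,
                            pathwaySizeRange = c(25, 100),
                            nBackgroundGenes = 500, delta = 2,
                            nActiveCase = 4, nActiveControl = 4,
                            plantedSets = list(list(
                              items = c("PW01:up", "PW02:up", "PW03:down"),
                              class = "case", penetrance = 0.8,
                              leak = 0.05)),
                            noiseSd = 1, methylationMirror = FALSE,
                            seed = 1) {
  cfg <- list(nCase = nCase, nControl = nControl, nPathways = nPathways,
              pathwaySizeRange = pathwaySizeRange,
              nBackgroundGenes = nBackgroundGenes, delta = delta,
              nActiveCase = nActiveCase, nActiveControl = nActiveControl,
              plantedSets = plantedSets, noiseSd = noiseSd,
              methylationMirror = methylationMirror, seed = seed)
  if (nCase < 2 || nControl < 2) stop("need at least 2 samples per class")
  if (pathwaySizeRange[1] < 1 || pathwaySizeRange[2] < pathwaySizeRange[1])
    stop("invalid pathwaySizeRange")
  plantedPw <- character()
  for (ps in plantedSets) {
    stopifnot(is.character(ps$items), length(ps$items) >= 1,
              ps$class %in% c("case", "control"))
    if (!(ps$penetrance > ps$leak))
      stop("penetrance must exceed leak rate")
    pw <- .parseItems(ps$items)$pathway
    plantedPw <- c(plantedPw, pw)
  }
  if (anyDuplicated(plantedPw))
    stop("a pathway may appear in at most one planted set")
  nReserved <- length(plantedPw) + nActiveCase + nActiveControl
  if (nReserved > nPathways)
    stop("nPathways too small for the planted/active pathways")
  class(cfg) <- "syntheticConfig"
  cfg
}

.pwName <- function(i) sprintf("PW%02d", i)

#' Generate a synthetic two-class omics dataset with ground truth
#'
#' See [syntheticConfig()] for the generative model. Pathway IDs are
#' `PW01..`; planted-set pathways keep the IDs named in the config's
#' `items`, class-wide active pathways take the next free IDs (case first),
#' the rest are pure-noise pathways. Identical config and seed give
#' byte-identical output.
#'
#' @param config a [syntheticConfig()].
#' @return list with `expression` ([OmicsMatrix-class]), `methylation`
#'   ([OmicsMatrix-class] or NULL), `geneSets`
#'   ([GeneSetCollection-class]), and `truth` (active pathways per class,
#'   planted sets, per-sample module indicators, gene assignment).
#' @export
generateSyntheticData <- function(config = syntheticConfig()) {
  stopifnot(inherits(config, "syntheticConfig"))
  set.seed(config$seed)
  nSamp <- config$nCase + config$nControl
  samples <- c(sprintf("Case%02d", seq_len(config$nCase)),
               sprintf("Ctrl%02d", seq_len(config$nControl)))
  labels <- setNames(rep(c("case", "control"),
                         c(config$nCase, config$nControl)), samples)

  allPw <- .pwName(seq_len(config$nPathways))
  plantedPw <- unique(unlist(lapply(config$plantedSets, function(ps)
    .parseItems(ps$items)$pathway)))
  if (!all(plantedPw %in% allPw))
    stop("planted set references a pathway beyond nPathways")
  free <- setdiff(allPw, plantedPw)
  activeCase <- head(free, config$nActiveCase)
  activeControl <- head(setdiff(free, activeCase), config$nActiveControl)

  sizes <- sample(seq(config$pathwaySizeRange[1], config$pathwaySizeRange[2]),
                  config$nPathways, replace = TRUE)
  names(sizes) <- allPw
  members <- setNames(vector("list", config$nPathways), allPw)
  for (p in allPw) {
    members[[p]] <- sprintf("%s_G%03d", p, seq_len(sizes[[p]]))
  }
  genes <- c(unlist(members, use.names = FALSE),
             if (config$nBackgroundGenes > 0)
               sprintf("BG%04d", seq_len(config$nBackgroundGenes)))

  values <- matrix(rnorm(length(genes) * nSamp, sd = config$noiseSd),
                   length(genes), nSamp,
                   dimnames = list(genes, samples))
  shifts <- matrix(0, length(genes), nSamp, dimnames = dimnames(values))
  for (p in activeCase) {
    shifts[members[[p]], labels == "case"] <-
      shifts[members[[p]], labels == "case"] + config$delta
  }
  for (p in activeControl) {
    shifts[members[[p]], labels == "control"] <-
      shifts[members[[p]], labels == "control"] + config$delta
  }
  moduleStates <- list()
  for (k in seq_along(config$plantedSets)) {
    ps <- config$plantedSets[[k]]
    pr <- ifelse(labels == ps$class, ps$penetrance, ps$leak)
    on <- rbinom(nSamp, 1L, pr) == 1L
    names(on) <- samples
    moduleStates[[k]] <- on
    parsed <- .parseItems(ps$items)
    for (j in seq_len(nrow(parsed))) {
      g <- members[[parsed$pathway[j]]]
      shifts[g, on] <- shifts[g, on] + parsed$sign[j] * config$delta
    }
  }
  expr <- OmicsMatrix(values + shifts, labels, "expression")

  meth <- NULL
  if (isTRUE(config$methylationMirror)) {
    methNoise <- matrix(rnorm(length(genes) * nSamp, sd = config$noiseSd),
                        length(genes), nSamp,
                        dimnames = list(genes, samples))
    meth <- OmicsMatrix(methNoise - shifts, labels, "methylation")
  }

  gsc <- GeneSetCollection(members,
                           setNames(sprintf("synthetic pathway %s", allPw),
                                    allPw))
  list(expression = expr, methylation = meth, geneSets = gsc,
       truth = list(activeCase = activeCase,
                    activeControl = activeControl,
                    plantedSets = config$plantedSets,
                    moduleStates = moduleStates,
                    members = members),
       config = config)
}

#' Write synthetic fixtures to plain-text files
#'
#' Writes the expression matrix (TSV), labels (TSV), gene sets (GMT), the
#' optional methylation matrix, and the ground truth (JSON) into a
#' directory.
#'
#' @param sim result of [generateSyntheticData()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSyntheticFixtures <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMatrixFile(sim$expression, file.path(dir, "expression.tsv"))
  lab <- sampleLabels(sim$expression)
  utils::write.table(data.frame(sample = names(lab), label = as.character(lab)),
                     file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeGMT(sim$geneSets, file.path(dir, "pathways.gmt"))
  if (!is.null(sim$methylation))
    writeMatrixFile(sim$methylation, file.path(dir, "methylation.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
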
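Package: panminer
Title: Mining Class-Specific Pathway-Set Markers and Pathway Activity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering class-specific associations among
    pathway activities from gene expression or DNA methylation data. Significant
    pathways are identified by permutation-based gene-set enrichment analysis
    with two ranking metrics (signal-to-noise ratio and t-statistic), pathway
    activities are inferred from condition-responsive member genes, discretized
    and binarized into up/down transaction items, and class-specific pathway-sets
    are mined with BiMax biclustering followed by association-rule filtering on
    support, confidence and lift. The selected pathway-set markers are evaluated
    as classification features under repeated stratified cross-validation and
    aggregated into per-class pathway activity networks (PANs) with
    significance-scaled nodes and co-occurrence-weighted edges. A synthetic data
    generator with full ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    igraph,
    jsonlite,
    e1071,
    randomForest,
    class
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
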
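# panminer

Disease markers are usually sought as single genes or single gene sets
(pathways). `panminer` targets the layer above: **pathway-sets** — groups
of direction-annotated pathways that are frequently active *together* in
one class of samples (case or control) — and the **pathway activity
networks (PANs)** they induce. It is aimed at researchers with a
gene-level expression or methylation matrix, binary case/control labels
and a GMT gene-set collection who want class-specific pathway
co-activation signatures, classification markers built from them, and a
per-class network view of the result.

## Method

For a matrix *X* (genes × samples) with labels *y* ∈ {case, control} and
a pathway collection *P*:

1. **Active pathways.** Genes are ranked by SNR = (μ₁−μ₂)/(σ₁+σ₂) and by
   the Welch t statistic; each pathway gets a weighted Kolmogorov–Smirnov
   enrichment score ES and an empirical p-value from phenotype
   permutations, p = (1 + #{|ES_π| ≥ |ES|})/(1 + n_π), with
   Benjamini–Hochberg q-values across pathways. Pathways with q < 0.05
   under **both** metrics are significant; with paired expression and
   methylation data the union of the two significant sets is used.
2. **Pathway activity.** For each significant pathway, a
   condition-responsive gene subset S is grown greedily over z-scored,
   sign-aligned member genes while |t| of a_S = Σ_{g∈S} z_g /√|S|
   strictly increases; a_S is the pathway's per-sample activity.
3. **Discretize and binarize.** Activities become ±1 at the per-pathway
   median, then a 2n-bit transaction column per sample (bits 1..n =
   up-regulated / hyper-methylated, bits n+1..2n = down / hypo).
4. **Mine pathway-sets.** BiMax-style enumeration of inclusion-maximal
   all-ones submatrices per class (≥ 2 pathways, ≥ 25% of class samples)
   yields candidate rules {signed pathway-set} ⇒ {class}, kept when
   confidence ≥ 0.8 and lift > 1, deduplicated across classes and ranked
   lift-first; the top 250 per class are the markers.
5. **Evaluate and aggregate.** Markers serve as features in stratified
   4-fold × 8-repetition cross-validation (kNN, SVM, random forest,
   naive Bayes; sensitivity/specificity/accuracy in percent, paired
   t-tests between marker types), and aggregate into per-class PANs with
   −log₂(p)-sized nodes and co-occurrence-weighted edges.

A synthetic generator (`generateSyntheticData()`) produces two-class data
with planted active pathways and planted co-activated pathway-sets plus
full ground truth, so the whole pipeline is testable without downloads.
See `vignettes/pathway-set-mining.Rmd` for the modelling details and
design choices.

## Worked example

```r
library(panminer)

sim <- generateSyntheticData(syntheticConfig(seed = 1))
om  <- zeroMeanNormalize(sim$expression)
snr <- permutationEnrichment(om, sim$geneSets, "snr",   nPerm = 1000, seed = 1)
tt  <- permutationEnrichment(om, sim$geneSets, "tstat", nPerm = 1000, seed = 1)
(sig <- selectSignificantPathways(snr, tt, 0.05))
#>  [1] "PW01" "PW02" "PW04" "PW05" "PW06" "PW07" "PW08" "PW09" "PW10" "PW11"
#> [11] "PW03"
```

Eleven pathways come out significant: the three members of the planted
case pathway-set (PW01–PW03) and the eight class-wide active pathways
(PW04–PW11); the 29 noise pathways are rejected. Mining the discretized
activities:

```r
prof    <- pathwayActivityProfile(om, sim$geneSets, sig)
states  <- discretizeActivity(prof)
markers <- minePathwaySetMarkers(binarize(states))
head(markers[, c("itemset", "class", "support", "confidence", "lift", "rank")], 4)
#>                                         itemset class support confidence lift rank
#> 1 PW04:up|...|PW11:down                    case   0.500          1    2    1
#> 2 PW01:up|PW02:up|PW04:up|...|PW11:down    case   0.450          1    2    2
#> 3 PW03:down|PW04:up|...|PW11:down          case   0.450          1    2    3
#> 4 PW01:up|PW02:up|PW03:down|...|PW11:down  case   0.425          1    2    4
```

The rank-4 case marker is exactly the planted signed set
{PW01↑, PW02↑, PW03↓} joined by the class-wide active pathways (up in
case, the control-active ones down); confidence 1 means every covered
sample is a case, and lift 2 is the maximum attainable with balanced
classes. The markers aggregate into a case PAN and classify perfectly on
this strongly separated simulation:

```r
buildPAN(markers, prof, states, "case")
#> PAN [case]: 11 nodes, 55 edges

feats <- buildFeatureMatrix("pathway_sets", markers, profile = prof)
rownames(feats) <- colnames(activityValues(prof))
crossValidate(feats, sampleLabels(om))@summary[, c("classifier", "accuracy.mean", "accuracy.sd")]
#>    classifier accuracy.mean accuracy.sd
#> 1         knn           100           0
#> 2 naive_bayes           100           0
#> 3          rf           100           0
#> 4         svm           100           0
```

A command-line front end with `simulate` / `gsea` / `activity` / `mine` /
`rules` / `pan` subcommands is installed at
`system.file("scripts", "panminer", package = "panminer")`.

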
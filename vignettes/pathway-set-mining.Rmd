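---
title: "Mining class-specific pathway-sets and pathway activity networks"
author: "panminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining class-specific pathway-sets and pathway activity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panminer)
```

# The problem

Individual genes and individual gene sets (pathways) are the classic units
of disease-marker discovery, but neither captures *associations between
pathway activities*: groups of pathways that tend to be active together in
one class of samples (say, tumours) and not in the other. `panminer`
implements a pipeline that discovers such **pathway-sets** from a
gene-by-sample expression or methylation matrix with binary case/control
labels, evaluates them as classification markers, and aggregates them into
per-class **pathway activity networks (PANs)**.

The stages are:

1. **Preprocessing** — probe collapsing by averaging, variance filtering,
   row z-scoring (`prepareOmicsMatrix()`).
2. **Active-pathway detection** — permutation GSEA with two ranking
   metrics (SNR and Welch t); a pathway is significant when its FDR q-value
   is below the cutoff under *both* metrics
   (`permutationEnrichment()`, `selectSignificantPathways()`). With paired
   expression and methylation data the final set is the union across the
   two data types (`unionAcrossDatatypes()`).
3. **Pathway activity inference** — a condition-responsive-genes (CORG)
   scheme: the most discriminative member-gene subset defines a per-sample
   scalar activity (`inferPathwayActivity()`).
4. **Discretization and binarization** — activities become ±1 states at
   the per-pathway median, then a 2n-item 0/1 transaction matrix with one
   "up" and one "down" item per pathway (`discretizeActivity()`,
   `binarize()`).
5. **Biclustering + rule mining** — inclusion-maximal all-ones submatrices
   of each class's columns (BiMax semantics, `bimax()`) become candidate
   rules `{signed pathway-set} => {class}`, filtered by confidence >= 0.8
   and lift > 1, deduplicated across classes and ranked by interestingness
   (`generateRules()`, `rankAndSelect()`).
6. **Evaluation** — marker types (genes / pathways / pathway-sets) are
   compared as classification features under stratified 4-fold
   cross-validation repeated 8 times with kNN, SVM, random forest and
   Gaussian naive Bayes (`crossValidate()`), and paired t-tests between
   accuracy series (`pairedTTestAccuracies()`).
7. **Networks** — per class, markers aggregate into a PAN whose nodes are
   pathways sized by `-log2(p)` of the class difference of their activity
   and whose edges are weighted by co-occurrence frequency across markers
   (`buildPAN()`, `exportPAN()`).

# Models and conventions, stage by stage

## Preprocessing

Multiple probes mapping to one gene are replaced by their arithmetic mean.
Rows with sample variance below a threshold are removed; the default
threshold is 0 (filter off) because no universally sensible value exists —
it is a data-dependent knob. Normalization both centres **and** unit-scales
each row. Centring alone would leave genes on different scales, and the
CORG aggregation below sums gene values, which is only meaningful for
comparably scaled genes; z-scoring is therefore the package's reading of
"zero-mean normalization". Zero-variance rows cannot be z-scored and are
an error (filter them first); missing values are an error, never imputed.

## Enrichment

The enrichment score is the weighted Kolmogorov–Smirnov running-sum
statistic: genes are ranked by the class-contrast metric, member-gene hits
increment the sum by `|metric|^p` (default `p = 1`) normalized by the total
hit weight, misses decrement by `1/(N - Nh)`, and the score is the signed
maximum absolute deviation. The SNR metric floors each group standard
deviation at `max(0.2 * |group mean|, 1e-8)` so near-constant genes cannot
dominate the ranking.

Significance uses *phenotype* permutations (class labels are what the
method contrasts, and permuting them preserves gene–gene correlation),
with the add-one empirical estimator
`p = (1 + #{|ES_perm| >= |ES_obs|}) / (1 + n_perm)` and
Benjamini–Hochberg adjustment across sets. This BH-on-empirical-p route
was chosen over the NES-pool FDR of classical GSEA implementations: it is
simpler, monotone in p, and directly testable for calibration. Defaults:
`nPerm = 1000`, minimum 5 member genes present in the matrix (smaller sets
give degenerate running sums), and the permutation seed is recorded in the
result's attributes. When fewer distinct label assignments exist than
requested permutations, all distinct ones are used and a warning is
raised.

## Pathway activity (CORG)

Member genes are z-scored, ordered by decreasing `|t|` (Welch), and
sign-aligned so that genes moving down in cases contribute positively.
Genes are then accepted greedily into the subset S while the `|t|` of the
running activity `a_S = colSums(z_S)/sqrt(|S|)` strictly increases; the
`sqrt(|S|)` scaling keeps the statistic comparable across subset sizes.
The search stops at the first non-improving gene, so it terminates in at
most `|members|` steps and its score trajectory is strictly increasing —
both properties are tested, and on small instances the greedy optimum is
checked against exhaustive subset enumeration.

Because sign-alignment alone would make every pathway look "up" in cases,
the final activity is re-oriented to the majority direction of the
selected genes (ties resolved by the most discriminative gene). A pathway
whose members drop in tumours therefore has *low* activity in tumours and
discretizes to a `:down` item there, which is what the up/down arrows in
mined pathway-sets and the red/blue node colouring of PANs rely on.

Discretization thresholds at the per-pathway **median** rather than zero:
it balances the two states, is robust to skewed activity distributions,
and makes the states invariant to monotone transformations of each row.
Ties go down (-1). For methylation data the same machinery applies with
+1 read as hyper- and -1 as hypo-methylation.

The activity of a *pathway-set* uses the same greedy scheme one level up:
pathway activity rows are z-scored, sign-aligned by the set's recorded
up/down annotation, ordered and accepted by the absolute **moderated t**
of the combined activity. The moderated t shrinks per-feature variances
towards a common prior (estimated with `limma::squeezeVar` when at least
30 features are available; with fewer features the prior weight is zero
and the statistic reduces exactly to the pooled t), which keeps the
statistic stable at small sample sizes.

## Expression–methylation inverse relationships

A pathway is *inverse* for a class when the majority discretized state
over that class's samples in expression is opposite to the majority state
in methylation. Each data type uses its own sample set, so paired studies
with different sample counts per platform are handled; majority ties count
as "not inverse".

## Biclustering

Inclusion-maximal all-ones submatrices of a binary matrix are exactly its
*closed itemsets* (itemset = all rows that are 1 on every column of the
cover; cover = all columns that are 1 on every row of the itemset).
`maximalBiclusters()` enumerates them once each by depth-first search with
prefix-preserving closure extensions, pruning covers below the sample
threshold. This enumeration is provably equivalent to the divide-and-
conquer BiMax output; the package pins the semantics with an independent
brute-force oracle (`bruteForceBiclusters()`, exhaustive over all item
subsets) and tests set-equality on hundreds of random matrices.

Mining runs separately on case columns and control columns of the full
2n-item matrix; the encoding invariant (exactly one of a pathway's two
bits per sample) guarantees an up and a down item of the same pathway can
never co-cluster. The support constraint is **class-relative**: a
bicluster must cover at least `ceil(minSupport * n_class)` of the mined
class's samples, default `minSupport = 0.25`. Output order is canonical
(most samples, then most items, then lexicographic items) for
reproducibility.

## Rules and markers

Rule metrics are ratios of integer counts over **all** N samples: support
`= |cover ∩ class| / N`, confidence `= |cover ∩ class| / |cover|`, lift
`= confidence / (n_class / N)`. Class-relative bicluster support and
all-sample rule support are deliberately distinct quantities and are
reported separately. Threshold boundaries are decided on the counts
themselves: confidence exactly at the cutoff (default 0.8) **passes** the
inclusive test, lift exactly at the cutoff (default 1) **fails** the
strict test; comparisons carry a 1e-9 guard so floating-point decimals
cannot flip a genuine rational boundary.

When an itemset is mined in both classes only the more significant rule
survives: higher lift first (lift is the only class-contrast measure of
the three), then confidence, then support; a complete tie keeps the case
rule with a warning. Ranking within a class uses the same lift-first
tuple, extended by itemset size and the lexicographic itemset key so that
identical inputs give byte-identical marker files; the top `topN`
(default 250) per class become the markers. Only maximal itemsets are
emitted as rules — sub-itemsets of a maximal bicluster are not re-scored.

## PANs

Nodes are the pathways occurring in at least one of the class's markers.
Node significance is `-log2(p)` with p from a **Welch** t-test on the
continuous activity between classes (deliberately not the moderated t, so
node size does not depend on how many other pathways happen to be in the
profile), floored at `p = 1e-300`. Node direction is the majority
discretized state over the class's samples (ties: down). Edges ignore
item direction — `A:up–B:down` and `A:up–B:up` both contribute to edge
A–B, since direction is a node property in the figures this mirrors — and
are weighted by marker count containing both endpoints divided by the
class's total marker count. GraphML and JSON exports are lossless;
SIF is a convenience export with a weight sidecar.

## Classification protocol

Stratified 4-fold cross-validation, 8 repetitions; repetition r partitions
with seed `seed + r - 1` (default seed 1 gives repetition seeds 1..8).
Per repetition, test-fold predictions pool into one confusion matrix;
sensitivity (on case), specificity (on control) and accuracy are means
(sd) over repetitions, in percent. Classifier settings — kNN k = 3
(Euclidean), linear SVM C = 1, random forest 500 trees, Gaussian naive
Bayes — are recorded in the report. Pathway-set features default to
fold-internal refitting: the pathway combination is re-fit on training
samples only and projected onto the test fold
(`pathwaySetFeatureBuilder()`); a fixed full-data feature matrix
(`buildFeatureMatrix()`) is also available for the variant where markers
are defined once on the full data set. Paired t-tests with zero-variance
differences (identical or constant-shifted accuracy series) are reported
as `NaN` rather than a fabricated p-value.

# The synthetic data generator

`generateSyntheticData()` produces the statistical structure the pipeline
assumes, with complete ground truth. Defaults describe a moderate
two-class microarray study: 40 case + 40 control samples, 40 pathways of
25–100 member genes drawn disjoint, 500 unassigned background genes,
iid N(0, 1) noise, and effect size `delta = 2` (in noise-sd units —
a clearly detectable but not degenerate microarray-scale effect). Signal
comes as

* **active pathways**: members shifted by `delta` in every sample of one
  class (4 per class by default), and
* **planted pathway-sets**: a per-sample Bernoulli "module on" indicator
  (penetrance 0.8 in the set's class, leak 0.05 in the other — a strong
  but imperfect co-activation) shared by the set's pathways, each shifted
  by `±delta` according to its up/down annotation. The default plants
  `{PW01:up, PW02:up, PW03:down} => case`.

The optional methylation mirror applies every shift with flipped sign to
a second noise matrix, emulating the inverse expression–methylation
relationship. Identical config + seed reproduce the data byte for byte.

What the generator does **not** emulate: probe-level noise and probe
multiplicity, batch effects, correlated background genes, overlapping
pathway memberships, non-Gaussian marginals, and class-imbalanced designs.
Passing tests on this generator therefore demonstrate correctness of the
algorithms under their stated assumptions, not robustness to real
microarray artefacts.

# Numerical choices and problem sizes

* Z-scoring in the CORG machinery maps constant rows to all-zero rather
  than NaN; boundary comparisons in rule filtering use integer counts
  with a 1e-9 guard; normalization idempotence and row-mean-zero are
  asserted at 1e-9; serialization fidelity at 1e-12.
* Tie-breaks are fixed and documented everywhere randomness could creep
  in: discretization ties go down, PAN direction ties go down, cross-class
  rule ties keep case, ranking falls back to the lexicographic itemset.
* The test and acceptance runs use deliberately moderate sizes chosen to
  exercise every code path at full statistical fidelity: oracle
  equivalence on 200 random 8–10 item × 12 sample matrices; GSEA
  calibration on 50 pathways × 80 samples with 1000 permutations over 20
  seeds; end-to-end recovery of the planted signed set on 100 seeded
  40+40-sample datasets; encoding invariants on 1000 random state
  matrices.

# Worked example

```{r example, eval = FALSE}
sim <- generateSyntheticData(syntheticConfig(seed = 1,
                                             methylationMirror = TRUE))
om   <- zeroMeanNormalize(sim$expression)
snr  <- permutationEnrichment(om, sim$geneSets, "snr",   nPerm = 1000)
tt   <- permutationEnrichment(om, sim$geneSets, "tstat", nPerm = 1000)
sig  <- selectSignificantPathways(snr, tt, 0.05)

prof    <- pathwayActivityProfile(om, sim$geneSets, sig)
states  <- discretizeActivity(prof)
markers <- minePathwaySetMarkers(binarize(states))

pan <- buildPAN(markers, prof, states, "case")
exportPAN(pan, "pan_case.graphml", "graphml")

feats <- buildFeatureMatrix("pathway_sets", markers, profile = prof)
rownames(feats) <- colnames(activityValues(prof))
crossValidate(feats, sampleLabels(om))
```

# Known limitations

* Only two-class designs; no multi-class or continuous phenotypes.
* The GSEA stage reports neither leading-edge subsets nor NES; gene
  permutation is not offered.
* Only the two-group moderated t is implemented, not the full linear-model
  framework of limma (no contrasts or array weights).
* Rule mining emits maximal itemsets only; redundancy beyond exact
  duplicates (e.g. near-identical itemsets) is not pruned.
* Bicluster enumeration is exact and exponential in the worst case; with
  very many weakly-structured pathways the closed-itemset count — and the
  marker count — grows sharply, which is precisely why markers are capped
  at the top-n per class.
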
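---
title: "Cross-species conserved markers and conservation specificity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species conserved markers and conservation specificity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Two Visium-style spatial transcriptomics datasets — one per species — cover
the same organ (the motivating case is the adrenal gland in human and
mouse, with its concentric cortical zones ZG, ZF and an inner zone that is
ZR in human but abuts brown adipose tissue in mouse).  Two questions drive
the package:

1. **Which canonical zone markers are conserved across the species?**
   A conserved marker must be differentially enriched in the matching
   cluster of *both* species, not just one.
2. **How specific is a cross-species gene signature for one cluster?**
   A signature shared by, say, the inner cortical zone of species A and a
   fat-rich cluster of species B could in principle reflect generic
   adipose or metabolic programs; specificity must be quantified against
   the other clusters and against random gene sets.

All analysis operates on spot-level counts: a spot is one capture location
holding a small multicellular neighborhood.

# Pipeline model

## Quality control and harmonization

Spots are restricted to tissue-covered positions, then genes are kept only
when detected (count > 0) in at least 1% of the remaining spots
(inclusive boundary; `min_gene_fraction = 0.01`).  Species B symbols are
mapped to species A symbols through a user-supplied (or simulated)
ortholog table; unmapped genes are dropped, because every cross-species
step needs shared identifiers, and when two sources map to one target the
later occurrences get deterministic `.1`, `.2`, … suffixes so identifiers
stay unique without ever merging counts.  An HGNC symbol-update table can
be applied through the same mechanism.

## Normalization

`log_normalize()` computes `ln(1 + count / total * 10^4)` per spot — the
counts-per-10k log transform that removes sequencing-depth differences.
The invariant `sum(expm1(values)) == 10^4` per non-empty spot is tested on
every generator output.  Natural log is the ecosystem convention; the
scale factor is a parameter.

## Joint embedding: design choice

The two species must be clustered *together* so cluster identities align.
The package does not re-implement anchor-based integration.  The default
embedding (`joint_pca(method = "cca")`) standardizes each gene within its
species and takes the SVD of the cross-species covariance matrix over
shared genes — a diagonal canonical correlation analysis.  Spots are
embedded through the singular vectors weighted by the singular values
(canonical scores), so the coordinates capture *shared* covariation only.

This choice was forced by measurement, not taste: a plain stacked PCA over
jointly standardized genes (`method = "pca"`, still available) leaves
species-private expression programs in the embedding, and on synthetic
data with planted species-specific markers every anatomical zone split
into two species-pure clusters — the cross-species cluster intersection
was empty and no conserved marker could be tested.  With the CCA
embedding the same data yield species-balanced, zone-pure clusters
(adjusted Rand index ≈ 1 on the default synthetic world).

Thirty components are kept by default.  Jackstraw-style component
selection is deliberately not implemented; the component count is a fixed,
documented parameter.

## Graph clustering

A shared-nearest-neighbor graph is built from the embedding: each spot's
`k = 20` nearest Euclidean neighbors (self included), edge weight the
Jaccard similarity of neighbor sets, edges below `1/15` pruned.  Louvain
modularity optimization at `resolution = 0.4` partitions the graph;
labels are renumbered by decreasing cluster size and the run is
deterministic given a seed.  `k` and the prune threshold are package
defaults (the upstream description names neither); both are exposed.
One practical caveat surfaced in testing: modularity clustering of a kNN
graph splits even a homogeneous point cloud once `k` is much smaller than
the cloud, so `k` should be chosen on the scale of the smallest expected
cluster.  Users can bypass clustering entirely by supplying labels (or
the generator's truth table).

## Conserved markers

Per cluster and species, one-vs-rest differential expression
(`cluster_marker_stats()`):

* **p-value** — two-sided Wilcoxon rank-sum test.  When both groups hold
  at most 25 spots the p-value is exact, from the tie-aware rank-sum
  distribution computed by dynamic programming (verified against full
  enumeration); otherwise the normal approximation with tie and
  continuity corrections is used.  Bonferroni adjustment over tested
  genes is the default (`BH` available).
* **avg_log2FC** — `log2((mean(expm1 values) in + 1) / (mean out + 1))`;
  the pseudocount of 1 on the counts-per-10k scale is a mild regularizer
  and is configurable.
* **pct_1 / pct_2** — detection fractions inside / outside the cluster.

`combine_conserved()` restricts to genes tested in both species and adds
the meta-analytic combination `minimump_p_val = 1 - (1 - min(p))^2`
(Tippett's minimum-p over two studies, clipped to `[1e-300, 1]`) and
`max_pval = max(p_a, p_b)`.  `filter_and_rank()` keeps genes with
`avg_log2FC > 1` **and** `pct_1 > 0.1` in **both** species (strict
inequalities, matching the stated cutoffs) and ranks by

```
rang = (-log2(minimump_p_val)) * (pct_1_a + pct_1_b) * (log2FC_a + log2FC_b)/2
```

sorted descending, ties broken by gene symbol.  Whether the published
ranking used the combined p or the smaller per-species adjusted p is not
fully determined by the upstream description; the combined raw p is the
default here and the interpretation is recorded as an open question.
Only `pct_1` is constrained (the cutoff is described "within the
identified clusters"); `pct_2` is reported but not filtered.

## Conservation specificity

* **Module score** (`score_module()`): genes are ranked by mean
  normalized expression and cut into 24 equal-frequency bins; each
  signature gene draws 100 control genes (with replacement, seeded) from
  its bin, signature genes themselves excluded from the control pool so
  the score is exactly linear in a constant shift of the signature; the
  spot score is mean(signature) − mean(pooled controls).  Bin and control
  counts follow the scoring function's conventional defaults since the
  upstream description names the function without parameters.
* **AUC** (`roc_auc()`): the normalized Mann–Whitney statistic — the
  fraction of (positive, negative) spot pairs where the positive scores
  higher, ties counting one half — with the target cluster as the
  positive class.
* **Profile correlations**: one-vs-rest log2 fold-change profiles per
  cluster (same code path as the marker statistics), Spearman-correlated
  with the reference species' target-cluster profile over the signature
  genes (average ranks for ties; missing genes dropped pairwise, at
  least 3 required).
* **Specificity margin**: `delta_rho = rho(target) − max(rho(others))`;
  negative when the target is not the best-correlated cluster.
* **Permutation null** (`permutation_test()`): 5000 iterations, each
  sampling 18 genes *without replacement* from the background of
  expressed genes (those surviving the 1% filter in both profiles),
  recomputing the Spearman correlation.  The empirical p is the plain
  proportion of permuted correlations at or above the observed one
  (`k / n_perm`; this matches the published arithmetic `3/5000 = 6e-4`),
  with the `(k+1)/(n+1)` estimator behind a flag.  Whether the observed
  value itself counts as an exceedance is not stated upstream; it does
  not count here.

# The synthetic world

The generator exists to exercise the pipeline with known truth; it is a
stated world, not a fitted model of any particular dataset.

* **Geometry** — a 41×41 lattice, concentric zones at radii
  (5, 9, 13, 16, 18) around the center: medulla, inner zone, ZF, ZG and a
  connective/white-adipose rim; ~1000 in-tissue spots per species,
  matching the order of magnitude of one capture area.  Species B
  additionally carries a 7×7 off-gland patch labelled as the inner zone
  (brown adipose tissue outside the gland).  Off-tissue lattice spots are
  generated with reduced library size and removed by QC.
* **Counts** — negative binomial, `mu = baseline * library_factor *
  fold`, `size = 2`.  Baselines are log-normal: background genes
  `meanlog = log(0.5), sdlog = 1`; marker genes `meanlog = log(2),
  sdlog = 0.5`, reflecting that usable zonal markers are
  moderately-to-well expressed.  Library factors are log-normal
  (`sdlog = 0.3`) so normalization has something to correct.
* **Markers** — 30 per zone and species: 20 conserved plus 10 per
  species-specific side.  Fold changes are uniform on [4, 16] (no
  effect-size distribution is published for real zonal markers; this
  range is a package choice).  A conserved marker draws **one** shared
  fold, diverged per species by a log-normal jitter (`sdlog = 0.2`):
  conservation without a shared effect-size ordering would be
  self-contradictory — with independent draws the planted signature's
  cross-species fold-change profiles decorrelate and the specificity
  analysis has nothing to detect.
* **Orthologs** — species-B genes are index-paired to species-A symbols;
  5% lose their mapping, and with probability 2% a target symbol
  receives a second source gene (flagged), exercising the duplicate
  suffix rule.
* **Signature** — the first 18 conserved inner-zone markers.
* A *null* configuration (`n_conserved_per_zone = 0`) removes all shared
  structure; under it the permutation p is uniform, which the acceptance
  suite verifies with a Kolmogorov–Smirnov test over 200 independent
  random signatures.

What the generator does **not** emulate: spatial autocorrelation within
zones, bleed-over between adjacent spots, cell-type mixtures within a
spot, batch chemistry effects, or histology images.  A green test
therefore establishes the statistical machinery on idealized zonal data,
not performance on any real tissue section.

# Numerical choices

* Combined p-values are clipped to `[1e-300, 1]` so `-log2` stays finite.
* Standardized values are clipped at ±10 before embedding; variable-gene
  standardized values at `sqrt(n_spots)`.
* Ranking ties break by gene symbol (stable, locale-independent C
  ordering of the synthetic symbols).
* All randomness (counts, ortholog perturbations, control-gene draws,
  permutations, Louvain) is governed by explicit seeds; a pipeline rerun
  with the same config and seed is byte-identical except for the log
  file's timestamp.

# Known limitations

* The CCA stand-in aligns species through linear shared covariation; it
  will not rescue datasets whose shared structure is nonlinear or
  dominated by technology differences the way anchor-based integration
  sometimes can.
* The exact Wilcoxon mode is quadratic in group size times rank-sum
  range; it is capped at 25 spots per group by default.
* Equal-frequency expression bins use rank ties broken by order, so
  module-score control pools can shift slightly under permutations of
  identical-mean genes.
* The tiny test fixture (6 conserved markers per zone) is below the
  sample size at which rank correlations over a signature stabilize;
  calibrated claims are asserted on the full-size world only.
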
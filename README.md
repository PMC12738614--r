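# orthomark

Cross-species conserved marker detection and conservation-specificity
analysis for Visium-style spatial transcriptomics.

## Who this is for

You have spot-level count matrices for the same organ in two species
(e.g. human and mouse adrenal gland), an ortholog table mapping one
species' gene symbols to the other's, and two questions:

1. Which canonical cluster/zone markers are **conserved** — enriched in
   the matching cluster of *both* species?
2. How **specific** is a cross-species gene signature for one cluster,
   compared with every other cluster and with random gene sets?

`orthomark` implements the full path from 10x-format files to ranked
conserved-marker tables and a permutation-tested specificity report, plus
a seeded two-species synthetic data generator so everything can be run
and tested without downloading anything.

## The statistics at the core

Per cluster and species, one-vs-rest differential expression gives a
two-sided Wilcoxon rank-sum p-value (exact for small groups), the fold
change `avg_log2FC = log2((mean(expm1 x)_in + 1)/(mean(expm1 x)_out + 1))`
and detection fractions `pct.1`, `pct.2`. Across species, p-values are
combined by Tippett's minimum-p rule `minimump_p_val = 1 − (1 − min p)²`;
genes with `avg_log2FC > 1` and `pct.1 > 0.1` in **both** species are kept
and ranked by

```
rang = (−log2 minimump_p_val) × (pct.1_a + pct.1_b) × (log2FC_a + log2FC_b)/2
```

Signature specificity is quantified by: a per-spot module score (mean
signature expression minus mean of expression-bin-matched control genes),
the ROC AUC of that score for the target cluster (Mann–Whitney pair
counting), Spearman correlations ρ between the reference cluster's log2FC
profile and every cluster's profile over the signature genes, the margin
Δρ = ρ(target) − max ρ(others), and an empirical p from 5000 random
18-gene sets drawn from the expressed background.

## Worked example

```r
library(orthomark)

# a full two-species synthetic dataset: ~1000 in-tissue spots/species,
# 1200 genes, 5 concentric zones, planted conserved + species-specific
# markers and a shared 18-gene inner-zone signature
res <- run_pipeline(pipeline_config(seed = 1), out_dir = "results/run1")
```

which logs, stage by stage (output printed by the code above):

```
simulate: 1681 + 1681 spots, 1200 genes/panel
qc: 1005/1054 in-tissue spots, 1200/1200 genes past the 1% filter
orthologs: 1135 species-B genes mapped
cluster: 5 clusters at resolution 0.4 over 1111 HVGs
markers: cluster 3 -> 15 conserved genes
markers: cluster 1 -> 18 conserved genes
markers: cluster 2 -> 19 conserved genes
markers: cluster 4 -> 20 conserved genes
markers: cluster 5 -> 19 conserved genes
specificity: AUC 1.000, rho 0.775, delta rho 1.406, p 0.0018
```

Reading this: joint CCA embedding + SNN/Louvain clustering recovered the
five planted zones (adjusted Rand index 1.0 vs truth here); per cluster,
15–20 genes passed the both-species conservation filter (100 were
planted, 20 per zone; recall 0.91, precision 1.0 at this seed); the
planted inner-zone signature scores highest in its own cluster (AUC 1.0),
its cross-species fold-change profiles correlate at ρ = 0.78, the margin
over the runner-up cluster is Δρ = 1.41, and only 9 of 5000 random
18-gene sets did as well (p = 0.0018).

Key outputs under `results/run1/`: `markers_<cluster>.tsv` (ranked
conserved markers: per-species p, log2FC, pct.1/pct.2, adjusted p,
then max_pval, minimump_p_val, sum, sumLog, rang), `dotplot.tsv`
(top-40 mean expression / detection per cluster and species),
`specificity.json` + `perm_rhos.tsv`, `cluster_labels.tsv`,
`manifest.json` (full config echo; reruns are byte-identical),
`gene_truth.tsv` / `spot_truth.tsv` (simulated runs only).

Real data: point `input_a` / `input_b` at 10x directories
(`matrix.mtx[.gz]`, `barcodes.tsv`, `features.tsv`,
`tissue_positions_list.csv`) and `ortholog_map` at a 2–3 column TSV, or
drive it from the command line:

```sh
Rscript inst/cli/orthomark.R run --config my.cfg --seed 1 --out results/
```

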
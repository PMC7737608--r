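# perturbscape

Interpreting transcription-factor perturbations on single-cell reference
landscapes, and assembling functional regulatory networks from CRISPR
knockout RNA-seq.

## The problem

Knocking out a transcription factor (TF) in a progenitor cell population
yields a table of differential expression (DE) — hundreds of log2 fold
changes with no obvious biological reading. Two complementary analyses
turn such tables into interpretable biology:

* **Direction-of-transition (DoT) scoring.** Given a single-cell
  reference landscape `E` (cells × genes, log-normalised) with a
  *viewpoint* cluster matching the perturbed population's starting state,
  scale the landscape to the viewpoint,
  `X = (E − mean_viewpoint) / sd_all_cells`, and score every reference
  cell against the perturbation's DE weight vector `v` (log2 fold
  changes): **s = Xv**. Positive scores mark cell states the perturbation
  pushes the origin population towards; negative scores mark transitions
  away. Significance comes from a permutation null — random gene sets of
  the same size, weighted from the pool of observed fold changes — giving
  each cell a z-score, and the linear score decomposes exactly into
  ranked per-gene contributions.
* **Network analytics.** From per-TF DE tables: TF→target edges requiring
  `padj < 0.1` and `|log2FC| > 0.2` in *both* a within-plate and an
  all-controls contrast; pairwise TF overlap z-scores under the matching
  hypergeometric distribution plus fold-change correlations;
  empirical-Bayes shrinkage of fold changes; target-module detection by
  average-linkage clustering on `1 − correlation` with a min-size-40 /
  cut-height-0.4 tree cut; ChIP peak-to-gene mapping (promoter > gene
  body > nearest gene within 50 kb) with binding/DE enrichment; and a
  negative-binomial two-factor interaction model
  `log2 mu = β0 + β1X1 + β2X2 + β3X1X2 + γ·intron_fraction`
  whose sign patterns classify gene-level interactions as additive,
  synergy, or buffering.

A synthetic-data module generates branched landscapes and replicated NB
perturbation experiments with known ground truth, so the whole pipeline
is testable end to end without any external download.

## Worked example

Score a signature pointing from the origin towards the neutrophil branch
of a synthetic three-branch landscape:

```r
library(perturbscape)

g   <- generate_landscape(landscape_spec(seed = 1))
g$landscape
#> Landscape: 550 cells x 120 genes, 16 clusters (viewpoint: origin)

sig <- signature_from_contrast(g$landscape, "neutrophil_5", "origin",
                               n_genes = 30)
res <- dot_score(g$landscape, sig, n_sim = 1000, seed = 1)
res
#> DoTResult: 550 cells, n_sim = 1000; z range [-4.97, 11.63]

sort(tapply(res$z, res$cluster, mean), decreasing = TRUE)[1:4]
#> neutrophil_5 neutrophil_4 neutrophil_3 neutrophil_2
#>        10.32         8.50         7.48         5.88

head(res$contributions$ranked[
  res$contributions$ranked$cluster == "neutrophil_5", ], 3)
#>          cluster           gene contribution rank
#> 421 neutrophil_5 neutrophil_g12    104.91259    1
#> 422 neutrophil_5 neutrophil_g15     93.36209    2
#> 423 neutrophil_5 neutrophil_g02     86.18584    3
```

The mean z-score rises monotonically along the neutrophil branch and
peaks at its tip — the perturbation is (correctly) read as pushing the
origin state towards the neutrophil fate — and the top contributing genes
in the tip cluster are that branch's lineage genes.

A thin command-line interface wraps the same functions
(`exec/perturbscape`): `simulate landscape|perturbation`, `dot`,
`project`, `network build`, `interactions fit`, each writing TSV outputs
plus a JSON provenance record.

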
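---
title: "Methods: DoT scoring and regulatory-network analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DoT scoring and regulatory-network analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perturbscape)
```

# Overview

`perturbscape` answers two questions about transcription-factor (TF)
perturbation experiments in progenitor cell systems:

1. **Where on a differentiation landscape is a perturbed population
   heading?** The direction-of-transition (DoT) score interprets a bulk
   perturbation signature on a single-cell reference landscape.
2. **What regulatory structure do many perturbations jointly reveal?** The
   network stage assembles TF→target edges from differential-expression
   (DE) tables, relates TFs pairwise, groups targets into modules,
   cross-references ChIP binding, and dissects double perturbations with a
   negative-binomial (NB) interaction model.

This vignette explains the models, their assumptions, the tunable
parameters, and the design decisions taken where choices were genuinely
open. All empirical statements below are computed by the package's test
suite or by `scripts/acceptance.R`; nothing is quoted from external runs.

# The DoT score

## Model

Let `E` be the log-normalised expression matrix of the reference landscape
(cells × genes) and let a *viewpoint* cluster designate the point of
origin — the reference population that best matches the perturbed cells'
starting state (for a lymphoid-primed progenitor line, the most
LMPP-like landscape cluster). Scaled expression is

```
X[c, g] = (E[c, g] − mean_viewpoint(g)) / sd_all_cells(g)
```

so each cell's row is the direction from the origin to that cell, in
units of per-gene spread. A perturbation contributes a weight vector `v`
of log2 fold changes (perturbed vs control) over its DE genes. The DoT
score is the per-cell dot product

```
s = X v
```

Positive `s` marks cell states the perturbation pushes the origin
population towards; negative `s` marks states it moves away from. Because
`s` is linear in `v`, signatures decompose exactly into per-gene
contributions (`gene_contributions()` is an exact ledger: per-cluster
contributions sum to the summed cell scores, to numerical tolerance).

Assumptions worth keeping in mind: the score is a straight arrow in
expression space anchored at the viewpoint — it does not follow the
curved cell-state manifold, so it should be read locally along
trajectories rather than as a global path; and it inherits whatever
biases the DE estimates carry.

## Permutation null and z-scores

Raw scores are not comparable across experiments (they scale with the DE
set size and effect magnitudes). `null_zscores()` calibrates them by
simulation: each of `n_sim` draws selects `n_de` genes uniformly
*without* replacement from the universe of expressed genes and assigns
each a weight drawn *with* replacement from the pool of all observed log2
fold changes. The per-cell z-score standardises the observed score by the
empirical null moments.

Choices made here (the sampling scheme is under-determined by the method
description alone): drawing genes without replacement mirrors "each gene
gets one weight", while reusing the observed fold-change pool keeps the
null's effect-size distribution realistic. The default `n_sim = 1000` is
the upper end of the 500–1,000 range typically used; at that depth the
t-inflation of empirical standardisation is negligible and, on null
signatures, per-cell z is approximately standard normal (the acceptance
suite checks a Kolmogorov–Smirnov statistic below 0.05 at 500 cells and a
5% tail rate within Monte Carlo error).

## Numerical choices

* **Which sd scales genes:** the origin-anchored *mean* is forced by the
  method; the sd is computed over **all** landscape cells (configurable in
  principle via the `Landscape` fields). A viewpoint-only sd would
  over-weight genes that are quiet in the origin but variable elsewhere —
  exactly the genes whose movement we want to see.
* **Clipping:** scaled values are clipped at ±10 to bound the leverage of
  outlier cells; configurable via `clip`.
* **Constant genes** (sd = 0) carry no direction and are dropped with a
  warning; **signature genes absent from the landscape** are dropped and
  counted, never imputed.
* **Universe:** defaults to all genes tested for DE (mean-expression
  filtering is the caller's choice when building the `DETable`).

# Projection of query transcriptomes

`fit_reference_pca()` jointly log-normalises and standardises reference
and query over their shared genes (per-gene moments from the concatenated
data), fits principal components on the *reference only* (default 50
components), and maps the query through the same transform.
`project_and_score()` finds each query cell's `k` nearest reference cells
by exact Euclidean distance in that space; a reference cell's projection
score is the number of times it is chosen, a relative-similarity map of
the query population. `k` defaults to 15; the neighbour counts used for
comparable graph-building tasks run 5–15 and the projection `k` is a free
tunable reported in provenance. Ties are broken by stable reference-cell
order; scores conserve exactly (`sum = k × n_query`).

# Network analytics

## Edge assembly

An edge TF→gene requires `padj < 0.1` and `|log2FC| > 0.2` in **both**
the within-plate contrast and the contrast against the assembly of all
controls; the dual filter suppresses plate-batch artefacts that a single
shared-control contrast would admit. Weights come from the within-plate
contrast. Both thresholds are exclusive on the fold-change side, and
loosening either threshold can only add edges (tested property).

## Pairwise TF statistics

For each TF pair we report the shared-target count, its z-score under the
matching hypergeometric distribution
(`z = (k − nK/N)/sqrt(nK(N−K)(N−n)/(N²(N−1)))`), and the Pearson
correlation of fold changes over shared targets (Spearman by flag; pairs
with fewer than 3 shared targets report `NA`). The gene universe for the
hypergeometric test defaults to all genes tested for DE — the natural
sampling frame for "targets drawn at random"; it is a declared parameter
because reasonable analyses could restrict to expressed genes. Both raw
and shrunken-fold-change correlations can be reported, since either is a
defensible basis for the pairwise comparison.

## Fold-change shrinkage

`shrink_lfc()` stabilises noisy estimates with a single-component normal
prior: `lfc ~ N(beta, se²)`, `beta ~ N(0, tau²)`, posterior mean
`lfc · tau²/(tau² + se²)`, with `tau²` estimated by marginal maximum
likelihood. This is a deliberate simplification of adaptive-shrinkage
mixtures: shrinkage here only stabilises correlations and clustering, and
the single-component prior preserves the property that matters — monotone
attenuation towards zero with sign preserved. Parameter recovery is tested
(within 20% at 5,000 genes).

## Target modules

Genes are clustered on their profile of shrunken fold changes across TFs
(restricting to well-connected TFs, e.g. >200 targets, is recommended):
average-linkage hierarchical clustering with `1 − correlation` distance,
tree cut at height 0.4, minimum module size 40 — the published defaults.
The cut is the simpler static-height variant of dynamic tree cutting:
clusters below the minimum size fall into the residual module 0, which
collects the (typically large) mass of genes without a shared pattern.
The hybrid variant's recursive adaptive cutting is not implemented; the
implementation is validated against planted block structure (adjusted
Rand index ≥ 0.9 across seeds) rather than bit-identity with any specific
software.

## Peaks and binding enrichment

Peak-to-gene assignment uses 0-based half-open coordinates and the
precedence promoter > gene body > nearest gene: a promoter window of
1,000 bp upstream to 200 bp downstream of the TSS (strand-aware), gene
body overlap, and for remaining intergenic peaks the single closest gene
within 50 kb. A peak may support several genes via promoter/body but only
one via nearest-gene. Binding/DE enrichment is computed separately for
up- and downregulated genes as observed/expected overlap with a
hypergeometric upper-tail p-value; empty DE sets are flagged rather than
scored.

# The interaction model

Double-perturbation counts are modelled per gene as NB with

```
log2 mu = beta0 + beta1·X1 + beta2·X2 + beta3·X1X2 + gamma·intron_fraction
```

plus a library-size offset (median-of-ratios factors by default). `beta3`
is the deviation of the double-perturbation effect from the sum of the
single effects. The GLM link is natural log; coefficients are converted
to log2 exactly (÷ ln 2). Dispersion is per-gene maximum likelihood with
a floor of 1e-4 and no cross-gene empirical-Bayes moderation — a
documented simplification: with ≥2 (typically 8) replicates per arm the
per-gene estimate is adequate for coefficient recovery, which is what the
classification consumes. Genes whose NB fit fails fall back to a Poisson
fit at the floor dispersion and are flagged, not dropped.

Classification uses the sign triplet (dir1, dir2, dirInt): **additive**
when the interaction direction is 0; **synergy** when all three agree
(combined effect exceeds the sum); **buffering** when the singles agree
and the interaction opposes them; **other** for remaining nonzero
patterns. Low stringency classifies only genes DE for both singles and
sets the interaction direction by the fold-change filter alone; high
stringency requires significance (padj < 0.1 and |log2FC| > 0.2) for
every direction. The raw triplet is always emitted because finer
groupings of the twelve nonzero patterns are analysis-dependent. The
intron-read fraction enters as a nuisance covariate because RNA-quality
variation correlates with intronic alignment and would otherwise
masquerade as expression change.

# Synthetic data: what it emulates and what it does not

`generate_landscape()` builds a branched landscape: an origin cluster and
(by default) three branches — labelled erythroid, neutrophil, lymphoid
after the classic marker triad — each with 5 position bins over which 20
branch-specific genes ramp linearly in log2 mean (maximum +2), plus 30
flat housekeeping and 30 low-expressed noise genes; counts are NB with
dispersion 0.2 (a realistic single-cell-like overdispersion for moderate
counts), 150 cells per branch and 100 origin cells by default. The ramp
makes the true direction of every cluster-contrast signature unambiguous,
which is what the direction-recovery tests require. The generator does
**not** emulate dropout/zero inflation, ambient RNA, doublets, batch
structure, or curved manifolds — so passing tests demonstrate the
correctness and calibration of the machinery, not robustness to every
real-data pathology.

`generate_perturbation_counts()` draws NB counts from the interaction
model itself with per-gene baselines log2-uniform in [4, 10], sparse
effects (30% of genes with N(0,1) single effects, 15% with interactions),
a per-gene intron-fraction coefficient (sd 0.25) over per-sample intron
fractions uniform in [0.15, 0.45], dispersion 0.1 and 8 replicates per
arm — the scale at which coefficient-recovery tests are run (mean
absolute bias of each effect below 0.05 log2 units at 500 genes). Because
data and model match by construction, these tests verify estimation, not
model adequacy on real libraries.

Problem sizes throughout the test-suite and acceptance script (500-cell
calibration landscapes, 40 direction-recovery runs, 500-gene interaction
recovery, 20-seed module benchmarks) were chosen as the smallest sizes at
which the Monte Carlo error of each check is comfortably below its
tolerance.

# Quality control and conventions

* QC rules (bulk samples): ≥ 500,000 reads, ≥ 30% exonic reads, ≤ 12%
  ERCC, ≤ 5% mitochondrial, ≥ 4,000 genes above 10 counts per million.
  The published filters state the *failure* side as strict inequalities,
  so boundary values pass; genes at exactly 10 CPM count as detected.
  This convention is documented because the inclusive/exclusive choice at
  the boundary is not otherwise determined.
* Gene identifiers are opaque strings; joins are exact (no cross-species
  mapping — that is the caller's job).
* TSV dialect: tab-separated, header row, UTF-8, `.` decimal. Counts
  travel as MatrixMarket coordinate files; peaks as BED (0-based
  half-open).
* Every CLI run writes a JSON provenance record (inputs, parameters,
  seed, version).

# Known limitations

* DoT is viewpoint-anchored and manifold-blind by design; interpret
  along trajectories, not across distant regions.
* The static-height tree cut can split a module that a hybrid adaptive
  cut would keep together when within-module correlation varies strongly.
* The single-component shrinkage prior under-shrinks when the true effect
  distribution is strongly multi-modal.
* The interaction model handles exactly two factors; guide-level random
  effects and more factors are out of scope.
* Exact brute-force neighbour search is quadratic; it is the default
  because correctness is testable, and an approximate backend can sit
  behind the same contract for large references.
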
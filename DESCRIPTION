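Package: perturbscape
Title: Interpreting Transcription-Factor Perturbations on Single-Cell
    Reference Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for interpreting perturbation-induced expression changes
    with single-cell reference landscapes and for assembling functional
    regulatory networks from CRISPR knockout RNA-seq. Implements the
    direction-of-transition (DoT) score: per-cell dot products of
    viewpoint-scaled landscape expression with a perturbation's log2
    fold-change signature, calibrated against a permutation null and
    decomposed into ranked gene contributions. Also provides query-to-reference
    projection in reference PCA space, differential-expression edge assembly
    with dual-control filtering, pairwise transcription-factor overlap
    statistics (hypergeometric z-scores and fold-change correlations),
    empirical-Bayes fold-change shrinkage, target-module detection by
    average-linkage clustering with a dynamic-style tree cut, ChIP peak-to-gene
    assignment with promoter/gene-body/nearest-gene precedence, binding versus
    differential-expression enrichment tests, a negative-binomial two-factor
    interaction model with synergy/buffering/additive classification, and a
    synthetic-data module generating branched landscapes and replicated
    negative-binomial perturbation experiments with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    methods,
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    DESeq2
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    yaml
Config/testthat/edition: 3
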
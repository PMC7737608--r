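#' Specification for a synthetic branched landscape
#'
#' Describes a simple branched differentiation landscape: a viewpoint
#' (origin) cluster plus several branches, each a sequence of position bins
#' along which that branch's lineage genes ramp up linearly in log2
#' expected expression. Housekeeping and noise genes are flat everywhere.
#' Counts are negative-binomial with a common dispersion.
#'
#' @param branches Branch (lineage) labels; at least 2 are required so a
#'   direction of transition is defined against an alternative fate.
#' @param n_cells_per_branch Cells per branch (split evenly over `n_bins`).
#' @param n_viewpoint_cells Cells in the origin cluster.
#' @param n_bins Position bins per branch (default 5).
#' @param genes_per_branch Lineage-specific genes per branch.
#' @param n_housekeeping,n_noise Flat gene counts (housekeeping are
#'   well-expressed; noise genes are low-expressed).
#' @param ramp_strength Maximum log2 increase of a lineage gene from the
#'   origin to the branch tip.
#' @param base_log2_mean,hk_log2_mean,noise_log2_mean Baseline log2 mean
#'   counts for lineage, housekeeping and noise genes.
#' @param nb_dispersion NB dispersion (Var = mu + dispersion * mu^2).
#' @param viewpoint Label of the origin cluster.
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A list of class `landscape_spec`.
#' @export
landscape_spec <- function(branches = c("erythroid", "neutrophil", "lymphoid"),
                           n_cells_per_branch = 150, n_viewpoint_cells = 100,
                           n_bins = 5, genes_per_branch = 20,
                           n_housekeeping = 30, n_noise = 30,
                           ramp_strength = 2, base_log2_mean = 4,
                           hk_log2_mean = 5, noise_log2_mean = 2,
                           nb_dispersion = 0.2, viewpoint = "origin",
                           seed = 1) {
  if (length(branches) < 2) {
    ps_stop("at least 2 branches required (a direction needs an alternative fate)",
            "ps_spec")
  }
  stopifnot(n_cells_per_branch > 0, n_viewpoint_cells > 0, n_bins > 0,
            genes_per_branch > 0, n_housekeeping > 0, n_noise > 0,
            nb_dispersion > 0)
  structure(as.list(environment()), class = "landscape_spec")
}

#' Generate a synthetic branched landscape
#'
#' Draws NB counts from the expected-expression model of [landscape_spec()]:
#' lineage genes of branch *b* ramp from `base_log2_mean` at the origin to
#' `base_log2_mean + ramp_strength` at the branch tip (linearly over
#' position bins), and are flat at baseline elsewhere. Cluster labels are
#' `viewpoint` for origin cells and `branch_bin` otherwise.
#'
#' @param spec A [landscape_spec()].
#' @return List with `counts` (a [count_matrix()] cells x genes),
#'   `landscape` (a [landscape()] built from log-normalised counts),
#'   `cell_truth` (data frame: cell, branch, bin) and `gene_truth`
#'   (data frame: gene, role in lineage/housekeeping/noise, branch).
#' @export
generate_landscape <- function(spec = landscape_spec()) {
  stopifnot(inherits(spec, "landscape_spec"))
  set.seed(spec$seed)
  nb <- length(spec$branches)
  bins_per_cell <- rep(seq_len(spec$n_bins),
                       length.out = spec$n_cells_per_branch)
  cell_truth <- rbind(
    data.frame(branch = spec$viewpoint, bin = 0L,
               n = spec$n_viewpoint_cells),
    do.call(rbind, lapply(spec$branches, function(b) {
      data.frame(branch = b, bin = sort(bins_per_cell), n = 1L)
    }))
  )
  cell_truth <- cell_truth[rep(seq_len(nrow(cell_truth)), cell_truth$n),
                           c("branch", "bin")]
  cell_truth$cell <- sprintf("cell%04d", seq_len(nrow(cell_truth)))
  rownames(cell_truth) <- NULL

  gene_truth <- rbind(
    do.call(rbind, lapply(spec$branches, function(b) {
      data.frame(gene = sprintf("%s_g%02d", b, seq_len(spec$genes_per_branch)),
                 role = "lineage", branch = b)
    })),
    data.frame(gene = sprintf("hk_g%02d", seq_len(spec$n_housekeeping)),
               role = "housekeeping", branch = NA_character_),
    data.frame(gene = sprintf("noise_g%02d", seq_len(spec$n_noise)),
               role = "noise", branch = NA_character_)
  )

  n_cells <- nrow(cell_truth)
  n_genes <- nrow(gene_truth)
  log2mu <- matrix(rep(ifelse(gene_truth$role == "housekeeping",
                              spec$hk_log2_mean,
                              ifelse(gene_truth$role == "noise",
                                     spec$noise_log2_mean,
                                     spec$base_log2_mean)),
                       each = n_cells),
                   nrow = n_cells)
  for (b in spec$branches) {
    gi <- which(gene_truth$branch %in% b)
    ci <- which(cell_truth$branch == b)
    ramp <- spec$ramp_strength * cell_truth$bin[ci] / spec$n_bins
    log2mu[ci, gi] <- log2mu[ci, gi] + ramp
  }
  mu <- 2^log2mu
  counts <- matrix(stats::rnbinom(n_cells * n_genes, mu = mu,
                                  size = 1 / spec$nb_dispersion),
                   nrow = n_cells,
                   dimnames = list(cell_truth$cell, gene_truth$gene))
  cm <- count_matrix(counts)
  cluster <- ifelse(cell_truth$bin == 0, spec$viewpoint,
                    paste0(cell_truth$branch, "_", cell_truth$bin))
  ls <- landscape(normalize_log(cm), cluster, spec$viewpoint)
  list(counts = cm, landscape = ls, cell_truth = cell_truth,
       gene_truth = gene_truth)
}

#' Design for a replicated two-factor perturbation experiment
#'
#' Encodes the generative side of the two-factor interaction model: per-gene
#' log2 baseline `beta0`, single-perturbation effects `beta1`, `beta2`,
#' interaction `beta3`, a per-gene coefficient `gamma` on the per-sample
#' intron-read fraction (a nuisance covariate mimicking RNA-quality
#' variation), and NB noise with dispersion `sigma`.
#'
#' Effects default to sparse draws: each gene receives a nonzero `beta1`
#' (`beta2`) with probability `effect_prob` and a nonzero `beta3` with
#' probability `interaction_prob`; nonzero values are N(0, `effect_sd`^2).
#' Explicit coefficient vectors can be supplied instead.
#'
#' @param n_genes Number of genes.
#' @param replicates Replicates per design arm (>= 2; four arms: control,
#'   perturbation 1, perturbation 2, double).
#' @param sigma NB dispersion (Var = mu + sigma * mu^2); default 0.1, a
#'   typical bulk RNA-seq scale.
#' @param beta0_range Uniform range for per-gene log2 baselines.
#' @param effect_prob,interaction_prob Probabilities of nonzero single /
#'   interaction effects.
#' @param effect_sd SD of nonzero effect draws (log2 units).
#' @param gamma_sd SD of the per-gene intron-fraction coefficient.
#' @param intron_range Uniform range of per-sample intron-read fractions.
#' @param beta0,beta1,beta2,beta3,gamma Optional explicit per-gene vectors
#'   overriding the random draws.
#' @param seed Integer seed.
#' @return A list of class `perturbation_design`.
#' @export
perturbation_design <- function(n_genes = 500, replicates = 8, sigma = 0.1,
                                beta0_range = c(4, 10), effect_prob = 0.3,
                                interaction_prob = 0.15, effect_sd = 1,
                                gamma_sd = 0.25, intron_range = c(0.15, 0.45),
                                beta0 = NULL, beta1 = NULL, beta2 = NULL,
                                beta3 = NULL, gamma = NULL, seed = 1) {
  if (replicates < 2) ps_stop("at least 2 replicates per arm required", "ps_spec")
  stopifnot(n_genes > 0, sigma > 0)
  structure(as.list(environment()), class = "perturbation_design")
}

#' Generate replicated NB counts for a two-factor perturbation experiment
#'
#' Counts follow `NB(mean = 2^(beta0 + beta1*X1 + beta2*X2 + beta3*X1*X2 +
#' gamma*intron_fraction), Var = mu + sigma*mu^2)` across the four design
#' arms, with `replicates` samples per arm.
#'
#' @param design A [perturbation_design()].
#' @return List with `counts` (a [count_matrix()] samples x genes), `meta`
#'   (data frame: sample_id, condition, x1, x2, intron_fraction) and
#'   `truth` (per-gene data frame of the generative coefficients).
#' @export
generate_perturbation_counts <- function(design = perturbation_design()) {
  stopifnot(inherits(design, "perturbation_design"))
  set.seed(design$seed)
  d <- design
  draw_sparse <- function(p) {
    stats::rnorm(d$n_genes, 0, d$effect_sd) *
      stats::rbinom(d$n_genes, 1, p)
  }
  beta0 <- if (is.null(d$beta0)) stats::runif(d$n_genes, d$beta0_range[1], d$beta0_range[2]) else d$beta0
  beta1 <- if (is.null(d$beta1)) draw_sparse(d$effect_prob) else d$beta1
  beta2 <- if (is.null(d$beta2)) draw_sparse(d$effect_prob) else d$beta2
  beta3 <- if (is.null(d$beta3)) draw_sparse(d$interaction_prob) else d$beta3
  gamma <- if (is.null(d$gamma)) stats::rnorm(d$n_genes, 0, d$gamma_sd) else d$gamma
  stopifnot(length(beta0) == d$n_genes, length(beta1) == d$n_genes,
            length(beta2) == d$n_genes, length(beta3) == d$n_genes,
            length(gamma) == d$n_genes)

  arms <- expand.grid(x1 = 0:1, x2 = 0:1)[c(1, 2, 3, 4), ]
  meta <- data.frame(
    x1 = rep(arms$x1, each = d$replicates),
    x2 = rep(arms$x2, each = d$replicates)
  )
  meta$condition <- paste0("x1:", meta$x1, "_x2:", meta$x2)
  meta$intron_fraction <- stats::runif(nrow(meta), d$intron_range[1],
                                       d$intron_range[2])
  meta$sample_id <- sprintf("s%03d", seq_len(nrow(meta)))
  meta <- meta[, c("sample_id", "condition", "x1", "x2", "intron_fraction")]

  log2mu <- outer(rep(1, nrow(meta)), beta0) +
    outer(meta$x1, beta1) + outer(meta$x2, beta2) +
    outer(meta$x1 * meta$x2, beta3) +
    outer(meta$intron_fraction, gamma)
  mu <- 2^log2mu
  if (any(!is.finite(mu))) ps_stop("non-finite NB mean in design", "ps_spec")
  genes <- sprintf("gene%04d", seq_len(d$n_genes))
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / d$sigma),
                   nrow = nrow(meta),
                   dimnames = list(meta$sample_id, genes))
  truth <- data.frame(gene = genes, beta0 = beta0, beta1 = beta1,
                      beta2 = beta2, beta3 = beta3, gamma = gamma,
                      sigma = d$sigma)
  list(counts = count_matrix(counts), meta = meta, truth = truth)
}

#' Signature from a contrast of two landscape clusters
#'
#' Builds a perturbation signature whose true direction is known: weights
#' are the mean log2 expression differences (cluster `cluster_a` minus
#' `cluster_b`) for the `n_genes` genes with the largest absolute
#' difference, plus optional Gaussian noise. The universe is all landscape
#' genes and the fold-change pool is the full vector of observed
#' differences.
#'
#' @param ls A [landscape()].
#' @param cluster_a,cluster_b Cluster labels to contrast (a - b). Typically
#'   `cluster_b` is the viewpoint, so the signature points towards
#'   `cluster_a`.
#' @param noise_sd SD of additive Gaussian noise on the weights (default 0).
#' @param n_genes Number of top-|difference| genes kept (default: all).
#' @return A [perturbation_signature()] with attribute `target_cluster`.
#' @export
signature_from_contrast <- function(ls, cluster_a, cluster_b, noise_sd = 0,
                                    n_genes = NULL) {
  stopifnot(inherits(ls, "Landscape"))
  for (cl in c(cluster_a, cluster_b)) {
    if (!cl %in% ls$cluster) ps_stop(paste0("cluster not present: ", cl), "ps_arg")
  }
  ma <- colMeans(ls$expr[ls$cluster == cluster_a, , drop = FALSE])
  mb <- colMeans(ls$expr[ls$cluster == cluster_b, , drop = FALSE])
  diff_log2 <- (ma - mb) / log(2)
  if (is.null(n_genes)) n_genes <- length(diff_log2)
  top <- utils::head(order(abs(diff_log2), decreasing = TRUE), n_genes)
  w <- diff_log2[top]
  if (noise_sd > 0) w <- w + stats::rnorm(length(w), 0, noise_sd)
  if (cluster_a == cluster_b && noise_sd == 0 && n_genes > 0) {
    warning("contrast of a cluster with itself: all-zero signature")
  }
  sig <- perturbation_signature(w, universe = colnames(ls$expr),
                                lfc_pool = unname(diff_log2))
  attr(sig, "target_cluster") <- cluster_a
  sig
}

#' Two-group NB differential-expression contrast
#'
#' Thin wrapper fitting a standard negative-binomial Wald contrast between
#' two sample groups (optionally with covariates), returning the
#' gene/log2fc/lfcSE/pvalue/padj table consumed by the network stage.
#' Intended for synthetic data and small fixtures; the main-screen DE
#' tables are inputs, not something this package recomputes.
#'
#' @param counts A [count_matrix()] (samples x genes).
#' @param condition Factor-like, length `nrow(counts)`; the contrast is
#'   second level versus first.
#' @param covariates Optional data frame of additional per-sample
#'   covariates (e.g. `intron_fraction`).
#' @return A `DETable` (BH-adjusted p-values).
#' @export
de_two_group <- function(counts, condition, covariates = NULL) {
  stopifnot(inherits(counts, "CountMatrix"))
  condition <- factor(condition)
  if (nlevels(condition) != 2) ps_stop("condition must have two levels", "ps_arg")
  col_data <- data.frame(condition = condition)
  design <- ~ condition
  if (!is.null(covariates)) {
    col_data <- cbind(col_data, covariates)
    design <- stats::as.formula(paste("~", paste(names(covariates), collapse = " + "),
                                      "+ condition"))
  }
  dds <- DESeq2::DESeqDataSetFromMatrix(
    countData = as.matrix(Matrix::t(counts$counts)), colData = col_data,
    design = design)
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  res <- DESeq2::results(dds, contrast = c("condition", levels(condition)[2],
                                           levels(condition)[1]))
  as_de_table(data.frame(gene = rownames(res), log2fc = res$log2FoldChange,
                         lfcSE = res$lfcSE, pvalue = res$pvalue,
                         padj = res$padj))
}
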
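#' Assemble TF-target edges from dual-control DE tables
#'
#' An edge TF -> gene is declared when the gene passes the differential-
#' expression filter (adjusted p below `padj_max` and |log2 fold change|
#' above `lfc_min`) in BOTH the primary (within-plate) contrast and the
#' contrast against the assembly of all controls; the dual filter damps
#' plate-level batch effects. Edge weights (signed log2 fold change) and
#' adjusted p-values are taken from the primary contrast.
#'
#' @param de_primary Named list of `DETable`s, one per TF (within-plate
#'   contrast).
#' @param de_allcontrols Named list of `DETable`s, one per TF (all-controls
#'   contrast); every TF in `de_primary` must have a companion table.
#' @param padj_max Adjusted-p threshold (default 0.1).
#' @param lfc_min Minimum |log2 fold change|, exclusive (default 0.2).
#' @return A `TFNetwork`: list with `edges` (data frame: tf, target,
#'   log2fc, padj), `tf_targets` (per-TF target counts), `gene_degree`
#'   (per-gene regulator counts) and the thresholds.
#' @export
assemble_edges <- function(de_primary, de_allcontrols, padj_max = 0.1,
                           lfc_min = 0.2) {
  tfs <- names(de_primary)
  if (is.null(tfs)) ps_stop("de_primary must be a named list of DE tables", "ps_arg")
  miss <- setdiff(tfs, names(de_allcontrols))
  if (length(miss)) {
    ps_stop(paste0("missing all-controls companion table for: ",
                   paste(miss, collapse = ", ")), "ps_missing_table")
  }
  passes <- function(de) {
    !is.na(de$padj) & de$padj < padj_max & abs(de$log2fc) > lfc_min
  }
  edges <- do.call(rbind, lapply(tfs, function(tf) {
    p <- as_de_table(de_primary[[tf]])
    a <- as_de_table(de_allcontrols[[tf]])
    ok_a <- a$gene[passes(a)]
    keep <- passes(p) & p$gene %in% ok_a
    if (!any(keep)) return(NULL)
    data.frame(tf = tf, target = p$gene[keep], log2fc = p$log2fc[keep],
               padj = p$padj[keep], row.names = NULL)
  }))
  if (is.null(edges)) {
    edges <- data.frame(tf = character(), target = character(),
                        log2fc = numeric(), padj = numeric())
  }
  structure(list(edges = edges,
                 tf_targets = table(factor(edges$tf, levels = tfs)),
                 gene_degree = table(edges$target),
                 padj_max = padj_max, lfc_min = lfc_min),
            class = "TFNetwork")
}

#' @export
print.TFNetwork <- function(x, ...) {
  cat(sprintf("TFNetwork: %d TFs, %d edges, %d target genes\n",
              length(x$tf_targets), nrow(x$edges),
              length(unique(x$edges$target))))
  invisible(x)
}

#' Hypergeometric overlap z-score
#'
#' Standardises an observed overlap `k` between a set of size `K` and a
#' set of size `n` drawn from a universe of size `N` by the mean and
#' variance of the matching hypergeometric distribution:
#' `z = (k - nK/N) / sqrt(nK(N-K)(N-n) / (N^2 (N-1)))`.
#'
#' @param k Observed overlap.
#' @param K,n Sizes of the two sets.
#' @param N Universe size.
#' @return List with `expected`, `z` and the upper-tail `p`
#'   (`P(overlap >= k)`).
#' @examples
#' hypergeom_overlap(3, K = 4, n = 5, N = 10)  # z ~ 1.2247
#' @export
hypergeom_overlap <- function(k, K, n, N) {
  k <- as.numeric(k); K <- as.numeric(K); n <- as.numeric(n); N <- as.numeric(N)
  if (N < K || N < n) ps_stop("universe smaller than a target set", "ps_universe")
  expected <- n * K / N
  v <- n * K * (N - K) * (N - n) / (N^2 * (N - 1))
  z <- if (v > 0) (k - expected) / sqrt(v) else 0
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(expected = expected, z = z, p = p)
}

#' Pairwise TF relationship statistics
#'
#' For every pair of TFs in a network: the shared-target count, its
#' hypergeometric z-score against the declared gene universe, and the
#' Pearson (or Spearman) correlation of edge log2 fold changes over the
#' shared targets. Pairs with fewer than 3 shared targets report a missing
#' correlation. If a TF x gene matrix of shrunken fold changes is supplied,
#' a second correlation over shared targets is computed from it.
#'
#' @param network A `TFNetwork` from [assemble_edges()].
#' @param universe_size Size of the gene universe tested for DE.
#' @param shrunken Optional numeric TF x gene matrix of shrunken log2 fold
#'   changes (rownames = TFs).
#' @param method Correlation type, `"pearson"` (default) or `"spearman"`.
#' @return Data frame: tf1, tf2, n_targets1, n_targets2, shared, expected,
#'   z, cor (and cor_shrunken when supplied).
#' @export
pairwise_tf_stats <- function(network, universe_size, shrunken = NULL,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(network, "TFNetwork"))
  tfs <- names(network$tf_targets)
  targets <- split(network$edges$target, factor(network$edges$tf, levels = tfs))
  lfc <- split(stats::setNames(network$edges$log2fc, network$edges$target),
               factor(network$edges$tf, levels = tfs))
  if (any(lengths(targets) > universe_size)) {
    ps_stop("universe smaller than a target set", "ps_universe")
  }
  pairs <- utils::combn(tfs, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    sh <- intersect(targets[[a]], targets[[b]])
    hg <- hypergeom_overlap(length(sh), length(targets[[a]]),
                            length(targets[[b]]), universe_size)
    cc <- if (length(sh) >= 3) {
      stats::cor(lfc[[a]][sh], lfc[[b]][sh], method = method)
    } else NA_real_
    row <- data.frame(tf1 = a, tf2 = b,
                      n_targets1 = length(targets[[a]]),
                      n_targets2 = length(targets[[b]]),
                      shared = length(sh), expected = hg$expected, z = hg$z,
                      cor = cc)
    if (!is.null(shrunken)) {
      sh2 <- intersect(sh, colnames(shrunken))
      row$cor_shrunken <- if (length(sh2) >= 3) {
        stats::cor(shrunken[a, sh2], shrunken[b, sh2], method = method)
      } else NA_real_
    }
    row
  }))
  rownames(out) <- NULL
  out
}

#' Empirical-Bayes shrinkage of log2 fold changes
#'
#' Stabilises noisy fold changes before correlation/clustering by
#' shrinking each estimate towards zero under a single-component normal
#' prior: with `lfc_g ~ N(beta_g, se_g^2)` and `beta_g ~ N(0, tau^2)`, the
#' posterior mean is `lfc_g * tau^2 / (tau^2 + se_g^2)`. The prior
#' variance `tau^2` is estimated by marginal maximum likelihood from the
#' (lfc, se) pairs. Shrinkage is monotone: `|shrunk| <= |lfc|`, sign
#' preserved (or zero).
#'
#' @param de A `DETable` with positive `lfcSE` values.
#' @return Named numeric vector of shrunken log2 fold changes, with the
#'   estimated `tau2` as an attribute.
#' @export
shrink_lfc <- function(de) {
  de <- as_de_table(de)
  ok <- is.finite(de$log2fc) & is.finite(de$lfcSE) & de$lfcSE > 0
  if (!any(ok)) ps_stop("all standard errors missing", "ps_de_schema")
  lfc <- de$log2fc[ok]
  se2 <- de$lfcSE[ok]^2
  nll <- function(log_tau2) {
    tot <- exp(log_tau2) + se2
    0.5 * sum(log(tot) + lfc^2 / tot)
  }
  opt <- stats::optimize(nll, interval = c(-25, 6))
  tau2 <- exp(opt$minimum)
  shrunk <- rep(NA_real_, nrow(de))
  shrunk[ok] <- lfc * tau2 / (tau2 + se2)
  names(shrunk) <- de$gene
  attr(shrunk, "tau2") <- tau2
  shrunk
}

#' Target-module detection by correlation clustering
#'
#' Clusters gene columns of a TF x gene (shrunken) fold-change matrix with
#' average-linkage hierarchical clustering on `1 - correlation` distance.
#' The tree is cut at a fixed height and clusters smaller than `min_size`
#' fall into the residual module 0, which collects genes without a clear
#' shared regulatory pattern (typically the majority). Remaining modules
#' are renumbered 1, 2, ... by decreasing size. Genes with an all-zero or
#' constant profile are assigned to module 0 up front.
#'
#' @param lfc_matrix Numeric TF x gene matrix (>= 2 TF rows).
#' @param min_size Minimum module size (default 40).
#' @param cut_height Tree cut height on the 1 - correlation scale, in
#'   (0, 2) (default 0.4).
#' @param method Correlation type for the distance (default Pearson).
#' @return A `ModuleAssignment`: list with `module` (named integer per
#'   gene; 0 = residual) and the clustering parameters.
#' @export
cluster_modules <- function(lfc_matrix, min_size = 40, cut_height = 0.4,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (cut_height <= 0 || cut_height >= 2) {
    ps_stop("cut_height must lie in (0, 2)", "ps_arg")
  }
  if (nrow(lfc_matrix) < 2) ps_stop("at least 2 TF rows required", "ps_arg")
  genes <- colnames(lfc_matrix)
  if (is.null(genes)) ps_stop("lfc_matrix needs gene colnames", "ps_arg")
  sds <- apply(lfc_matrix, 2, stats::sd)
  usable <- sds > 0 & colSums(abs(lfc_matrix)) > 0
  module <- stats::setNames(rep(0L, length(genes)), genes)
  if (sum(usable) >= 2) {
    cm <- stats::cor(lfc_matrix[, usable, drop = FALSE], method = method)
    d <- stats::as.dist(1 - cm)
    hc <- stats::hclust(d, method = "average")
    cl <- stats::cutree(hc, h = cut_height)
    sizes <- table(cl)
    big <- names(sizes)[sizes >= min_size]
    relabel <- stats::setNames(rep(0L, length(sizes)), names(sizes))
    ord <- big[order(-sizes[big], as.integer(big))]
    relabel[ord] <- seq_along(ord)
    module[names(cl)] <- relabel[as.character(cl)]
  }
  structure(list(module = module, min_size = min_size,
                 cut_height = cut_height, linkage = "average",
                 distance = paste0("1-", method, " correlation")),
            class = "ModuleAssignment")
}

#' @export
print.ModuleAssignment <- function(x, ...) {
  n_mod <- length(setdiff(unique(x$module), 0L))
  cat(sprintf("ModuleAssignment: %d genes, %d modules + residual (%d genes in module 0)\n",
              length(x$module), n_mod, sum(x$module == 0)))
  invisible(x)
}
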
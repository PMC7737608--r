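#' Construct a perturbation signature
#'
#' A `PerturbationSignature` carries the sparse per-gene weight vector of a
#' perturbation (log2 fold changes of perturbed versus control cells over
#' the differentially expressed gene set), the universe of genes eligible
#' for permutation-null draws, and the pool of all observed log2 fold
#' changes that null weights are drawn from.
#'
#' @param weights Named numeric vector of log2 fold changes (DE genes only).
#' @param universe Character vector of all expressed genes eligible for the
#'   null; must contain every weighted gene. Defaults to the weighted genes.
#' @param lfc_pool Numeric vector of observed log2 fold changes used for
#'   null weight draws. Defaults to `weights`.
#' @return An object of class `PerturbationSignature` with `weights`,
#'   `universe`, `lfc_pool` and `n_de` (the number of nonzero weights).
#' @export
perturbation_signature <- function(weights, universe = names(weights),
                                   lfc_pool = unname(weights)) {
  if (is.null(names(weights))) ps_stop("weights must be a named vector", "ps_arg")
  if (!all(names(weights) %in% universe)) {
    ps_stop("every weighted gene must be in the universe", "ps_universe")
  }
  structure(list(weights = weights, universe = unique(as.character(universe)),
                 lfc_pool = lfc_pool, n_de = sum(weights != 0)),
            class = "PerturbationSignature")
}

#' @export
print.PerturbationSignature <- function(x, ...) {
  cat(sprintf("PerturbationSignature: %d weighted genes (%d nonzero), universe %d, pool %d\n",
              length(x$weights), x$n_de, length(x$universe), length(x$lfc_pool)))
  invisible(x)
}

#' Build a signature from a DE table
#'
#' @param de A `DETable` (see [as_de_table()]).
#' @param padj_max,lfc_min DE thresholds selecting the weighted genes
#'   (defaults 0.1 and 0.2).
#' @param universe Gene universe for the null; defaults to all genes in the
#'   table (all genes tested for differential expression).
#' @return A [perturbation_signature()]. The null pool is the full vector of
#'   observed log2 fold changes across the table.
#' @export
signature_from_de <- function(de, padj_max = 0.1, lfc_min = 0.2,
                              universe = de$gene) {
  de <- as_de_table(de)
  keep <- !is.na(de$padj) & de$padj < padj_max & abs(de$log2fc) > lfc_min
  w <- stats::setNames(de$log2fc[keep], de$gene[keep])
  perturbation_signature(w, universe = universe,
                         lfc_pool = de$log2fc[is.finite(de$log2fc)])
}

#' Scale a landscape to its viewpoint
#'
#' Centres every gene on its mean over the viewpoint cluster and divides by
#' its standard deviation over all landscape cells, so a cell's scaled row
#' is the direction from the origin state to that cell in units of
#' per-gene spread. Values are clipped to `±clip` to bound outlier
#' leverage; genes with zero standard deviation carry no direction and are
#' dropped with a warning.
#'
#' @param ls A [landscape()].
#' @param clip Symmetric clipping bound on scaled values (default 10).
#' @return Scaled cells x genes matrix `X` (constant genes removed; dropped
#'   gene names in attribute `dropped_genes`).
#' @export
scale_to_viewpoint <- function(ls, clip = 10) {
  stopifnot(inherits(ls, "Landscape"))
  if (!any(ls$cluster == ls$viewpoint_cluster)) {
    ps_stop("viewpoint cluster is empty", "ps_viewpoint")
  }
  keep <- ls$gene_sd > 0
  if (any(!keep)) {
    warning(sum(!keep), " constant gene(s) dropped from scaling: ",
            paste(utils::head(colnames(ls$expr)[!keep], 5), collapse = ", "))
  }
  X <- sweep(ls$expr[, keep, drop = FALSE], 2, ls$gene_mean_viewpoint[keep], "-")
  X <- sweep(X, 2, ls$gene_sd[keep], "/")
  X[X > clip] <- clip
  X[X < -clip] <- -clip
  attr(X, "dropped_genes") <- colnames(ls$expr)[!keep]
  X
}

#' Direction-of-transition scores
#'
#' Computes the per-cell DoT score `s = X v`: for each reference cell, the
#' dot product of its viewpoint-scaled expression with the perturbation's
#' log2 fold-change weights. Positive scores mark cell states the
#' perturbation pushes the origin cell towards; negative scores mark
#' transitions away. Signature genes absent from the scaled matrix are
#' dropped (and counted in attribute `n_missing`).
#'
#' @param X Scaled cells x genes matrix from [scale_to_viewpoint()].
#' @param signature A [perturbation_signature()].
#' @return Named numeric vector of per-cell scores.
#' @export
compute_dot <- function(X, signature) {
  stopifnot(inherits(signature, "PerturbationSignature"))
  v <- signature$weights
  shared <- intersect(names(v), colnames(X))
  if (length(shared) == 0) {
    ps_stop(paste0("no signature genes present in the landscape; first missing: ",
                   paste(utils::head(names(v), 5), collapse = ", ")),
            "ps_no_shared_genes")
  }
  s <- as.vector(X[, shared, drop = FALSE] %*% v[shared])
  names(s) <- rownames(X)
  attr(s, "n_missing") <- length(v) - length(shared)
  s
}

#' Permutation-null z-scores for DoT scores
#'
#' Calibrates DoT scores against an empirical null built by repeatedly
#' assigning weights at random: each simulation draws `n_de` genes uniformly
#' without replacement from the signature's universe and gives each a weight
#' drawn (with replacement) from the pool of all observed log2 fold changes.
#' The per-cell z-score is the observed score standardised by the empirical
#' null mean and standard deviation.
#'
#' @param X Scaled cells x genes matrix from [scale_to_viewpoint()].
#' @param signature A [perturbation_signature()] with a populated universe
#'   and fold-change pool.
#' @param n_sim Number of null simulations (>= 100; default 1,000).
#' @param seed Integer seed for reproducibility.
#' @return A `DoTResult`: list with `scores`, `z`, `null_mean`, `null_sd`,
#'   `n_sim`, `seed` and `zero_sd_cells` (cells whose null sd was zero, with
#'   z forced to 0).
#' @export
null_zscores <- function(X, signature, n_sim = 1000, seed = NULL) {
  stopifnot(inherits(signature, "PerturbationSignature"))
  if (n_sim < 100) ps_stop("n_sim must be at least 100", "ps_arg")
  n_de <- signature$n_de
  universe <- signature$universe
  if (n_de > length(universe)) {
    ps_stop("more nonzero weights than genes in the universe", "ps_universe")
  }
  if (length(signature$lfc_pool) == 0) ps_stop("empty fold-change pool", "ps_arg")
  if (!is.null(seed)) set.seed(seed)

  s <- compute_dot(X, signature)
  # null scores for all simulations in one sparse multiply
  idx <- replicate(n_sim, sample.int(length(universe), n_de))
  pool <- signature$lfc_pool
  w <- matrix(pool[sample.int(length(pool), n_de * n_sim, replace = TRUE)],
              nrow = n_de)
  W <- Matrix::sparseMatrix(i = as.vector(idx),
                            j = rep(seq_len(n_sim), each = n_de),
                            x = as.vector(w),
                            dims = c(length(universe), n_sim))
  in_x <- universe %in% colnames(X)
  S <- as.matrix(X[, universe[in_x], drop = FALSE] %*% W[in_x, , drop = FALSE])
  null_mean <- rowMeans(S)
  null_sd <- sqrt(rowSums((S - null_mean)^2) / (n_sim - 1))
  z <- ifelse(null_sd > 0, (s - null_mean) / null_sd, 0)
  names(z) <- rownames(X)
  structure(list(scores = s, z = z, null_mean = null_mean, null_sd = null_sd,
                 n_sim = n_sim, seed = seed,
                 zero_sd_cells = rownames(X)[null_sd == 0]),
            class = "DoTResult")
}

#' @export
print.DoTResult <- function(x, ...) {
  cat(sprintf("DoTResult: %d cells, n_sim = %d; z range [%.2f, %.2f]\n",
              length(x$scores), x$n_sim, min(x$z), max(x$z)))
  invisible(x)
}

#' Per-gene contributions to DoT scores, summed by cluster
#'
#' Decomposes the score into its per-gene components: the contribution of a
#' gene in a cluster is the sum over the cluster's cells of scaled
#' expression times the gene's weight. Per-cluster contributions sum to the
#' summed cell scores of that cluster, so the table is an exact ledger of
#' where each cluster's score comes from.
#'
#' @param X Scaled cells x genes matrix.
#' @param signature A [perturbation_signature()].
#' @param clusters Cluster label per cell (length `nrow(X)`).
#' @param top_n Number of top genes per cluster in the ranked table
#'   (default 50).
#' @return List with `matrix` (gene x cluster contributions over all
#'   weighted genes present) and `ranked` (data frame: cluster, gene,
#'   contribution, rank by signed contribution, descending).
#' @export
gene_contributions <- function(X, signature, clusters, top_n = 50) {
  clusters <- as.character(clusters)
  if (length(clusters) != nrow(X)) {
    ps_stop("cluster labels must match the number of cells", "ps_arg")
  }
  v <- signature$weights
  shared <- intersect(names(v), colnames(X))
  if (length(shared) == 0) ps_stop("no signature genes present", "ps_no_shared_genes")
  labs <- sort(unique(clusters))
  contrib <- vapply(labs, function(cl) {
    colSums(X[clusters == cl, shared, drop = FALSE]) * v[shared]
  }, numeric(length(shared)))
  contrib <- matrix(contrib, nrow = length(shared),
                    dimnames = list(shared, labs))
  ranked <- do.call(rbind, lapply(labs, function(cl) {
    ord <- order(contrib[, cl], decreasing = TRUE)
    top <- utils::head(ord, top_n)
    data.frame(cluster = cl, gene = shared[top],
               contribution = contrib[top, cl],
               rank = seq_along(top), row.names = NULL)
  }))
  list(matrix = contrib, ranked = ranked)
}

#' End-to-end DoT analysis
#'
#' Convenience wrapper: scales the landscape to its viewpoint, computes
#' per-cell scores, calibrates against the permutation null and summarises
#' gene contributions by cluster.
#'
#' @inheritParams null_zscores
#' @param ls A [landscape()].
#' @param clip Clipping bound for [scale_to_viewpoint()].
#' @param top_n Top genes per cluster for [gene_contributions()].
#' @return A `DoTResult` with an added `contributions` element and the
#'   landscape's cluster labels in `cluster`.
#' @export
dot_score <- function(ls, signature, n_sim = 1000, seed = NULL, clip = 10,
                      top_n = 50) {
  X <- scale_to_viewpoint(ls, clip = clip)
  res <- null_zscores(X, signature, n_sim = n_sim, seed = seed)
  res$contributions <- gene_contributions(X, signature, ls$cluster, top_n = top_n)
  res$cluster <- ls$cluster
  res
}
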
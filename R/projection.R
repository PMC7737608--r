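#' Joint normalisation and reference PCA for cross-dataset projection
#'
#' Prepares a query dataset for projection onto a reference landscape:
#' both datasets are log-normalised (if given as counts), restricted to
#' their shared genes and standardised with per-gene mean/sd computed on
#' the concatenated data, then principal components are fitted on the
#' reference only and the query is mapped through the same transform.
#'
#' @param reference,query Either [count_matrix()] objects or plain
#'   cells x genes matrices of log-normalised expression with gene
#'   colnames.
#' @param n_components Number of principal components (default 50); must
#'   not exceed the feasible rank.
#' @param target_sum Row total used when normalising counts.
#' @return A list of class `projection_fit` with `ref_coords`,
#'   `query_coords` (cells x components), `rotation`, `genes` (shared genes
#'   used) and `n_components`.
#' @export
fit_reference_pca <- function(reference, query, n_components = 50,
                              target_sum = 1e4) {
  get_expr <- function(x) {
    if (inherits(x, "CountMatrix")) normalize_log(x, target_sum) else as.matrix(x)
  }
  ref <- get_expr(reference)
  qry <- get_expr(query)
  shared <- intersect(colnames(ref), colnames(qry))
  if (length(shared) < 2) ps_stop("fewer than 2 shared genes", "ps_shared_genes")
  ref <- ref[, shared, drop = FALSE]
  qry <- qry[, shared, drop = FALSE]
  joint <- rbind(ref, qry)
  mu <- colMeans(joint)
  sd <- apply(joint, 2, stats::sd)
  keep <- sd > 0
  ref <- sweep(sweep(ref[, keep, drop = FALSE], 2, mu[keep]), 2, sd[keep], "/")
  qry <- sweep(sweep(qry[, keep, drop = FALSE], 2, mu[keep]), 2, sd[keep], "/")
  max_comp <- min(nrow(ref) - 1, ncol(ref))
  if (n_components > max_comp) {
    ps_stop(sprintf("n_components = %d exceeds feasible rank %d",
                    n_components, max_comp), "ps_arg")
  }
  pca <- stats::prcomp(ref, center = TRUE, scale. = FALSE, rank. = n_components)
  query_coords <- sweep(qry, 2, pca$center) %*% pca$rotation
  structure(list(ref_coords = pca$x, query_coords = query_coords,
                 rotation = pca$rotation, genes = colnames(ref),
                 n_components = n_components),
            class = "projection_fit")
}

#' Project query cells and score reference cells
#'
#' Finds, for every query cell, its `k` nearest reference cells by
#' Euclidean distance in reference PCA space (exact brute-force search;
#' ties broken by reference-cell order, which is stable). The projection
#' score of a reference cell is the total number of times it is chosen as
#' a neighbour, reflecting relative transcriptional similarity to the
#' query population.
#'
#' @param fit A `projection_fit` from [fit_reference_pca()].
#' @param k Number of nearest neighbours per query cell (default 15).
#' @return A list of class `ProjectionResult` with `neighbors` (query x k
#'   matrix of reference indices), `distances` (matching matrix),
#'   `projection_score` (named integer per reference cell) and `k`.
#' @export
project_and_score <- function(fit, k = 15) {
  stopifnot(inherits(fit, "projection_fit"))
  R <- fit$ref_coords
  Q <- fit$query_coords
  if (k < 1) ps_stop("k must be >= 1", "ps_arg")
  if (k > nrow(R)) {
    ps_stop(sprintf("k = %d exceeds the %d reference cells", k, nrow(R)), "ps_arg")
  }
  d2 <- outer(rowSums(Q^2), rep(1, nrow(R))) +
    outer(rep(1, nrow(Q)), rowSums(R^2)) - 2 * Q %*% t(R)
  d2[d2 < 0] <- 0
  nn <- t(apply(d2, 1, function(d) order(d)[seq_len(k)]))
  if (k == 1) nn <- matrix(nn, ncol = 1)
  nd <- sqrt(t(vapply(seq_len(nrow(Q)),
                      function(i) d2[i, nn[i, ]], numeric(k))))
  if (k == 1) nd <- matrix(nd, ncol = 1)
  score <- tabulate(as.vector(nn), nbins = nrow(R))
  names(score) <- rownames(R)
  rownames(nn) <- rownames(Q)
  structure(list(neighbors = nn, distances = nd,
                 projection_score = score, k = k),
            class = "ProjectionResult")
}

#' @export
print.ProjectionResult <- function(x, ...) {
  cat(sprintf("ProjectionResult: %d query cells, k = %d, %d reference cells hit\n",
              nrow(x$neighbors), x$k, sum(x$projection_score > 0)))
  invisible(x)
}
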
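#' Construct a reference Landscape
#'
#' A `Landscape` bundles log-normalised expression for reference cells with
#' cluster labels, a designated viewpoint cluster (the point of origin for
#' direction-of-transition scoring), per-gene scaling statistics and an
#' optional 2-D embedding. The viewpoint mean anchors the scaling: scaled
#' expression measures how far each cell lies from the origin state, in
#' units of the gene's landscape-wide standard deviation.
#'
#' @param expr Numeric matrix, cells x genes, log-normalised expression with
#'   cell and gene dimnames.
#' @param cluster Cluster label per cell (character or factor, length
#'   `nrow(expr)`).
#' @param viewpoint_cluster One of the labels in `cluster`.
#' @param embedding Optional cells x 2 matrix of embedding coordinates.
#' @return An object of class `Landscape` with elements `expr`, `cluster`,
#'   `viewpoint_cluster`, `gene_mean_viewpoint` (per-gene mean over viewpoint
#'   cells), `gene_sd` (per-gene sd over all cells) and `embedding`.
#' @export
landscape <- function(expr, cluster, viewpoint_cluster, embedding = NULL) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    ps_stop("expr needs cell rownames and gene colnames", "ps_arg")
  }
  cluster <- as.character(cluster)
  if (length(cluster) != nrow(expr)) {
    ps_stop("cluster labels must match the number of cells", "ps_arg")
  }
  if (!viewpoint_cluster %in% cluster) {
    ps_stop(paste0("viewpoint cluster not present: ", viewpoint_cluster),
            "ps_viewpoint")
  }
  vp <- cluster == viewpoint_cluster
  gene_mean_viewpoint <- colMeans(expr[vp, , drop = FALSE])
  gene_sd <- apply(expr, 2, stats::sd)
  if (!is.null(embedding)) {
    embedding <- as.matrix(embedding)
    stopifnot(nrow(embedding) == nrow(expr), ncol(embedding) == 2)
  }
  structure(list(expr = expr, cluster = cluster,
                 viewpoint_cluster = viewpoint_cluster,
                 gene_mean_viewpoint = gene_mean_viewpoint,
                 gene_sd = gene_sd, embedding = embedding),
            class = "Landscape")
}

#' @export
print.Landscape <- function(x, ...) {
  cat(sprintf("Landscape: %d cells x %d genes, %d clusters (viewpoint: %s)\n",
              nrow(x$expr), ncol(x$expr), length(unique(x$cluster)),
              x$viewpoint_cluster))
  invisible(x)
}
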
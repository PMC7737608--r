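# Shared fixtures and independent oracles, all built in code.

# small landscape spec for fast unit tests
small_spec <- function(seed = 1, ...) {
  landscape_spec(n_cells_per_branch = 50, n_viewpoint_cells = 40,
                 genes_per_branch = 15, n_housekeeping = 20, n_noise = 20,
                 seed = seed, ...)
}

# naive per-cell dot-product loop (oracle for compute_dot)
naive_dot <- function(X, weights) {
  shared <- intersect(names(weights), colnames(X))
  out <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    acc <- 0
    for (g in shared) acc <- acc + X[i, g] * weights[[g]]
    out[i] <- acc
  }
  names(out) <- rownames(X)
  out
}

# exact hypergeometric moments and upper tail by direct pmf enumeration
enum_hypergeom <- function(k, K, n, N) {
  ks <- max(0, n + K - N):min(n, K)
  pmf <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  mu <- sum(ks * pmf)
  v <- sum((ks - mu)^2 * pmf)
  list(expected = mu, z = if (v > 0) (k - mu) / sqrt(v) else 0,
       p = sum(pmf[ks >= k]))
}

# random DE table
random_de_table <- function(n = 50, seed = 1, prefix = "g") {
  set.seed(seed)
  data.frame(gene = paste0(prefix, seq_len(n)),
             log2fc = rnorm(n, 0, 0.5),
             lfcSE = runif(n, 0.05, 0.3),
             pvalue = runif(n),
             padj = runif(n))
}

# planted two-block TF x gene fold-change matrix (module benchmark);
# block genes share a TF profile up to small noise, background genes are
# independent noise
planted_module_matrix <- function(seed = 1, n_tf = 10, block = 50,
                                  n_background = 0, noise = 0.1) {
  set.seed(seed)
  p1 <- rnorm(n_tf)
  p2 <- rnorm(n_tf)
  # the benchmark plants blocks with across-block correlation ~ 0:
  # orthogonalise the second profile against the first
  p1c <- p1 - mean(p1)
  p2 <- p2 - mean(p2) - sum((p2 - mean(p2)) * p1c) / sum(p1c^2) * p1c
  m <- cbind(
    outer(p1, rep(1, block)) + matrix(rnorm(n_tf * block, 0, noise), n_tf),
    outer(p2, rep(1, block)) + matrix(rnorm(n_tf * block, 0, noise), n_tf),
    if (n_background > 0) matrix(rnorm(n_tf * n_background), n_tf, n_background)
  )
  colnames(m) <- paste0("g", seq_len(ncol(m)))
  truth <- rep(c(1L, 2L, 0L), c(block, block, n_background))
  list(matrix = m, truth = truth)
}

# draw a signature from the permutation-null generator (n_de genes uniform
# without replacement, weights with replacement from the pool)
draw_null_signature <- function(sig, n_de = sig$n_de) {
  genes <- sample(sig$universe, n_de)
  w <- setNames(sig$lfc_pool[sample.int(length(sig$lfc_pool), n_de,
                                        replace = TRUE)], genes)
  perturbation_signature(w, universe = sig$universe, lfc_pool = sig$lfc_pool)
}
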
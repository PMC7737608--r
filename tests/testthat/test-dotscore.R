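make_scaled_toy <- function() {
  expr <- rbind(c(1, 1, 1), c(2, 1, 0), c(1, 2, 1), c(0, 1, 2), c(1, 0, 1))
  dimnames(expr) <- list(paste0("c", 1:5), c("gA", "gB", "gC"))
  landscape(expr, cluster = c("vp", "vp", "b1", "b2", "b2"),
            viewpoint_cluster = "vp")
}

test_that("viewpoint scaling centres, scales, clips, and drops constant genes", {
  ls <- make_scaled_toy()
  X <- scale_to_viewpoint(ls)
  # a cell equal to the viewpoint mean scales to zero
  vp_mean <- colMeans(ls$expr[1:2, ])
  ls2 <- landscape(rbind(ls$expr, cM = vp_mean), c(ls$cluster, "b1"), "vp")
  X2 <- scale_to_viewpoint(ls2)
  expect_equal(unname(X2["cM", ]), rep(0, 3))

  # direct formula: expr 2.0, viewpoint mean 1.0, sd 1.0 -> 1.0
  expr <- matrix(c(1, 1, 2, 1, 0, 1), ncol = 1,
                 dimnames = list(paste0("c", 1:6), "g"))
  lsd <- landscape(expr, c("vp", "vp", "x", "x", "x", "x"), "vp")
  lsd$gene_sd[] <- 1  # pin sd to make the formula explicit
  Xd <- scale_to_viewpoint(lsd)
  expect_equal(unname(Xd["c3", "g"]), 1.0)

  # constant gene dropped with a warning
  exprc <- cbind(ls$expr, gK = rep(3, 5))
  lsc <- landscape(exprc, ls$cluster, "vp")
  expect_warning(Xc <- scale_to_viewpoint(lsc), "constant gene")
  expect_false("gK" %in% colnames(Xc))
  expect_identical(attr(Xc, "dropped_genes"), "gK")

  # clipping bounds leverage
  exprb <- ls$expr; exprb[3, 1] <- 1e3
  lsb <- landscape(exprb, ls$cluster, "vp")
  expect_lte(max(abs(scale_to_viewpoint(lsb, clip = 5))), 5)
})

test_that("compute_dot matches hand dot products and flags missing genes", {
  X <- matrix(c(1, -1, 0), nrow = 1, dimnames = list("c1", c("gA", "gB", "gC")))
  sig <- perturbation_signature(c(gA = 0.5, gB = -0.5, gC = 0))
  expect_equal(as.numeric(compute_dot(X, sig)), 1.0)

  zero <- perturbation_signature(c(gA = 0, gB = 0))
  expect_equal(as.numeric(compute_dot(X, zero)), 0)

  off <- perturbation_signature(c(gZ = 1, gA = 0.5))
  s <- compute_dot(X, off)
  expect_equal(attr(s, "n_missing"), 1L)
  all_off <- perturbation_signature(c(gZ = 1, gY = 2))
  expect_error(compute_dot(X, all_off), "no signature genes")
})

test_that("compute_dot equals the naive per-cell loop on random matrices", {
  set.seed(17)
  for (rep in 1:3) {
    X <- matrix(rnorm(50 * 100), 50, 100,
                dimnames = list(sprintf("c%02d", 1:50), sprintf("g%03d", 1:100)))
    w <- setNames(rnorm(30), sample(colnames(X), 30))
    sig <- perturbation_signature(w, universe = colnames(X))
    expect_equal(compute_dot(X, sig), naive_dot(X, w),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("a lineage-marker signature points into the marked branch", {
  # three-marker toy: positive weight on the neutrophil marker only
  g <- generate_landscape(small_spec(seed = 33))
  ls <- g$landscape
  marker <- g$gene_truth$gene[g$gene_truth$branch %in% "neutrophil"][1]
  sig <- perturbation_signature(
    setNames(c(1, 0, 0),
             c(marker,
               g$gene_truth$gene[g$gene_truth$branch %in% "erythroid"][1],
               g$gene_truth$gene[g$gene_truth$branch %in% "lymphoid"][1])),
    universe = colnames(ls$expr))
  s <- compute_dot(scale_to_viewpoint(ls), sig)
  top_cell <- names(which.max(s))
  expect_match(g$cell_truth$branch[g$cell_truth$cell == top_cell], "neutrophil")
})

test_that("null z-scores match an independent re-implementation exactly", {
  ls <- make_scaled_toy()
  X <- scale_to_viewpoint(ls)
  sig <- perturbation_signature(c(gA = 0.4, gB = -0.7),
                                universe = colnames(X),
                                lfc_pool = c(0.4, -0.7, 0.2, -0.1, 0.9))
  res <- null_zscores(X, sig, n_sim = 100, seed = 99)

  # straightforward second implementation sharing only the draw order
  set.seed(99)
  idx <- replicate(100, sample.int(length(sig$universe), 2))
  w <- matrix(sig$lfc_pool[sample.int(5, 200, replace = TRUE)], nrow = 2)
  null_scores <- matrix(0, nrow(X), 100)
  for (j in 1:100) {
    for (r in 1:2) {
      gene <- sig$universe[idx[r, j]]
      if (gene %in% colnames(X)) {
        null_scores[, j] <- null_scores[, j] + X[, gene] * w[r, j]
      }
    }
  }
  s <- naive_dot(X, sig$weights)
  m <- rowMeans(null_scores)
  sdv <- apply(null_scores, 1, sd)
  z <- ifelse(sdv > 0, (s - m) / sdv, 0)
  expect_equal(unname(res$z), unname(z), tolerance = 1e-12)
  expect_equal(unname(res$null_mean), m, tolerance = 1e-12)
})

test_that("z-scores honour their defining identity and edge cases", {
  g <- generate_landscape(small_spec(seed = 2))
  sig <- signature_from_contrast(g$landscape, "erythroid_5", "origin",
                                 n_genes = 20)
  X <- scale_to_viewpoint(g$landscape)
  res <- null_zscores(X, sig, n_sim = 150, seed = 5)
  ok <- res$null_sd > 0
  expect_equal(res$z[ok] * res$null_sd[ok] + res$null_mean[ok],
               res$scores[ok], tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(null_zscores(X, sig, n_sim = 50), "at least 100")
  too_many <- perturbation_signature(
    setNames(rep(1, 3), c("gA", "gB", "gC")),
    universe = c("gA", "gB", "gC"))
  too_many$n_de <- 10
  expect_error(null_zscores(X, too_many, n_sim = 100), "universe")
})

test_that("DoT is linear in the signature and invariant to axis permutations", {
  set.seed(41)
  X <- matrix(rnorm(30 * 40), 30, 40,
              dimnames = list(sprintf("c%02d", 1:30), sprintf("g%02d", 1:40)))
  u <- colnames(X)
  w1 <- setNames(rnorm(40), u)
  w2 <- setNames(rnorm(40), u)
  s1 <- compute_dot(X, perturbation_signature(w1))
  s2 <- compute_dot(X, perturbation_signature(w2))
  s12 <- compute_dot(X, perturbation_signature(w1 + w2))
  expect_equal(s12, s1 + s2, tolerance = 1e-12, ignore_attr = TRUE)

  pc <- sample(nrow(X)); pg <- sample(ncol(X))
  expect_equal(compute_dot(X[pc, ], perturbation_signature(w1)),
               s1[pc], tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(compute_dot(X[, pg], perturbation_signature(w1)),
               s1, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("gene contributions form an exact ledger of cluster scores", {
  g <- generate_landscape(small_spec(seed = 13))
  ls <- g$landscape
  sig <- signature_from_contrast(ls, "lymphoid_5", "origin", n_genes = 25)
  X <- scale_to_viewpoint(ls)
  s <- compute_dot(X, sig)
  contrib <- gene_contributions(X, sig, ls$cluster, top_n = 25)
  for (cl in unique(ls$cluster)) {
    expect_equal(sum(contrib$matrix[, cl]), sum(s[ls$cluster == cl]),
                 tolerance = 1e-9)
  }
  expect_error(gene_contributions(X, sig, ls$cluster[-1]), "match")

  # single-gene signature: that gene ranks first wherever expressed
  solo <- perturbation_signature(setNames(2, colnames(X)[1]),
                                 universe = colnames(X))
  ranked <- gene_contributions(X, solo, ls$cluster)$ranked
  expect_true(all(ranked$gene == colnames(X)[1]))

  # branch-tip signature is enriched for that branch's lineage genes
  top <- contrib$ranked[contrib$ranked$cluster == "lymphoid_5", "gene"][1:15]
  lineage <- g$gene_truth$gene[g$gene_truth$branch %in% "lymphoid"]
  k <- length(intersect(top, lineage))
  p <- phyper(k - 1, length(lineage), ncol(X) - length(lineage), 15,
              lower.tail = FALSE)
  expect_lt(p, 1e-6)
})

test_that("null-generator signatures produce approximately standard normal z", {
  spec <- small_spec(seed = 55)
  g <- generate_landscape(spec)
  base <- signature_from_contrast(g$landscape, "erythroid_5", "origin")
  X <- scale_to_viewpoint(g$landscape)
  set.seed(7)
  z <- unlist(lapply(1:4, function(i) {
    sig <- draw_null_signature(base, n_de = 40)
    null_zscores(X, sig, n_sim = 300, seed = 100 + i)$z
  }))
  ks <- suppressWarnings(stats::ks.test(z, "pnorm"))
  expect_lt(unname(ks$statistic), 0.08)
})
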
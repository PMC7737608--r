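toy_tables <- function() {
  # 20 genes; genes g1-g4 pass both contrasts, others fail one or both
  genes <- paste0("g", 1:20)
  primary <- data.frame(gene = genes,
                        log2fc = c(rep(0.3, 4), 0.15, rep(0.3, 5), rep(0.05, 10)),
                        lfcSE = 0.1,
                        pvalue = 0.01,
                        padj = c(rep(0.05, 10), rep(0.5, 10)))
  allctl <- primary
  allctl$padj[7:10] <- 0.9   # fails the all-controls contrast
  allctl$log2fc[6] <- 0.1    # fails the fold-change filter there
  list(primary = list(TFa = primary), allcontrols = list(TFa = allctl))
}

test_that("edges require passing both DE filters in both contrasts", {
  tt <- toy_tables()
  net <- assemble_edges(tt$primary, tt$allcontrols)
  # row-wise oracle: padj < 0.1 & |lfc| > 0.2 in both tables
  p <- tt$primary$TFa; a <- tt$allcontrols$TFa
  ok <- p$padj < 0.1 & abs(p$log2fc) > 0.2 & a$padj < 0.1 & abs(a$log2fc) > 0.2
  expect_setequal(net$edges$target, p$gene[ok])
  expect_equal(nrow(net$edges), 4)
  expect_true(all(net$edges$log2fc == 0.3))  # weights from the primary contrast

  # a gene at padj 0.05 / lfc 0.3 in both is an edge; lfc 0.15 is not
  expect_true("g1" %in% net$edges$target)
  expect_false("g5" %in% net$edges$target)
  expect_error(assemble_edges(tt$primary, list()), "missing all-controls")
})

test_that("loosening either threshold never removes an edge", {
  set.seed(23)
  tfs <- paste0("TF", 1:3)
  prim <- setNames(lapply(tfs, function(tf) random_de_table(80, seed = match(tf, tfs))), tfs)
  allc <- setNames(lapply(tfs, function(tf) random_de_table(80, seed = 10 + match(tf, tfs))), tfs)
  base <- assemble_edges(prim, allc, padj_max = 0.1, lfc_min = 0.2)
  for (loose in list(c(0.2, 0.2), c(0.1, 0.1), c(0.3, 0.05))) {
    net <- assemble_edges(prim, allc, padj_max = loose[1], lfc_min = loose[2])
    key <- function(e) paste(e$tf, e$target)
    expect_true(all(key(base$edges) %in% key(net$edges)))
  }
})

test_that("hypergeometric z and p agree with exact enumeration", {
  # worked instance
  hg <- hypergeom_overlap(3, K = 4, n = 5, N = 10)
  expect_equal(hg$expected, 2.0)
  expect_equal(hg$z, 1.2247, tolerance = 1e-4)

  # every instance with N <= 12, plus random instances up to N = 30
  for (N in 4:12) {
    for (K in 1:(N - 1)) for (n in 1:(N - 1)) {
      for (k in max(0, n + K - N):min(n, K)) {
        got <- hypergeom_overlap(k, K, n, N)
        want <- enum_hypergeom(k, K, n, N)
        expect_equal(got$z, want$z, tolerance = 1e-10)
        expect_equal(got$p, want$p, tolerance = 1e-10)
      }
    }
  }
  set.seed(19)
  for (i in 1:200) {
    N <- sample(13:30, 1); K <- sample(1:(N - 1), 1); n <- sample(1:(N - 1), 1)
    k <- sample(max(0, n + K - N):min(n, K), 1)
    got <- hypergeom_overlap(k, K, n, N)
    want <- enum_hypergeom(k, K, n, N)
    expect_equal(got$z, want$z, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
  expect_error(hypergeom_overlap(2, K = 12, n = 3, N = 10), "universe")
})

test_that("pairwise TF statistics report overlaps and correlations", {
  genes <- paste0("g", 1:30)
  de <- function(lfc_by_gene) {
    lfc <- rep(0, 30)
    lfc[match(names(lfc_by_gene), genes)] <- lfc_by_gene
    data.frame(gene = genes, log2fc = lfc, lfcSE = 0.1, pvalue = 0.5,
               padj = ifelse(lfc != 0, 0.01, 0.9))
  }
  # TFa and TFb share g1-g3 with exactly proportional fold changes
  prim <- list(
    TFa = de(c(g1 = 0.3, g2 = -0.25, g3 = 0.5, g4 = 0.4, g5 = 0.4)),
    TFb = de(c(g1 = 0.6, g2 = -0.5, g3 = 1.0)),
    TFc = de(c(g20 = 0.5, g21 = 0.5, g22 = 0.5, g23 = 0.5, g24 = 0.5)))
  net <- assemble_edges(prim, prim)
  st <- pairwise_tf_stats(net, universe_size = 30)
  ab <- st[st$tf1 == "TFa" & st$tf2 == "TFb", ]
  expect_equal(ab$shared, 3)
  expect_equal(ab$cor, 1.0, tolerance = 1e-12)  # exactly proportional
  ac <- st[st$tf1 == "TFa" & st$tf2 == "TFc", ]
  expect_equal(ac$shared, 0)                    # disjoint target sets
  expect_true(is.na(ac$cor))
  # z agrees with the exact moments
  want <- enum_hypergeom(3, 5, 3, 30)
  expect_equal(ab$z, want$z, tolerance = 1e-10)
})

test_that("shrinkage attenuates monotonically and recovers the prior variance", {
  de <- data.frame(gene = c("a", "b"), log2fc = c(1, 1),
                   lfcSE = c(1e-6, 100), pvalue = NA, padj = NA)
  s <- shrink_lfc(de)
  expect_equal(unname(s["a"]), 1, tolerance = 1e-3)   # se -> 0: no shrinkage
  expect_lt(abs(s["b"]), 0.01)                        # se >> tau: to zero

  set.seed(29)
  n <- 5000; tau2 <- 0.25
  se <- runif(n, 0.05, 0.4)
  de2 <- data.frame(gene = paste0("g", 1:n),
                    log2fc = rnorm(n, 0, sqrt(tau2 + se^2)),
                    lfcSE = se, pvalue = NA, padj = NA)
  s2 <- shrink_lfc(de2)
  expect_lt(abs(attr(s2, "tau2") - tau2) / tau2, 0.2)
  expect_true(all(abs(s2) <= abs(de2$log2fc)))
  expect_true(all(sign(s2) == sign(de2$log2fc) | s2 == 0))

  bad <- de; bad$lfcSE <- NA
  expect_error(shrink_lfc(bad), "standard errors")
})

test_that("planted fold-change blocks are recovered as pure modules", {
  fx <- planted_module_matrix(seed = 77, noise = 0.05)
  ma <- cluster_modules(fx$matrix)
  expect_equal(ma$min_size, 40)     # defaults match the published parameters
  expect_equal(ma$cut_height, 0.4)
  mods <- setdiff(unique(ma$module), 0L)
  expect_length(mods, 2)
  # block purity
  for (m in mods) {
    blocks <- fx$truth[ma$module == m]
    expect_equal(length(unique(blocks)), 1)
  }
})

test_that("undersized clusters fall into the residual module", {
  fx <- planted_module_matrix(seed = 78, block = 30)  # below min_size = 40
  ma <- cluster_modules(fx$matrix)
  expect_true(all(ma$module == 0))
  expect_error(cluster_modules(fx$matrix, cut_height = 2.5), "cut_height")
  expect_error(cluster_modules(fx$matrix[1, , drop = FALSE]), "2 TF rows")
})

test_that("module labels are equivalent under gene column permutation", {
  skip_if_not_installed("mclust")
  fx <- planted_module_matrix(seed = 79, n_background = 20, noise = 0.1)
  ma1 <- cluster_modules(fx$matrix)
  perm <- sample(ncol(fx$matrix))
  ma2 <- cluster_modules(fx$matrix[, perm])
  common <- colnames(fx$matrix)
  expect_equal(mclust::adjustedRandIndex(ma1$module[common], ma2$module[common]), 1)
})
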
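#' Fit the two-factor negative-binomial interaction model
#'
#' Fits, per gene, the NB log-linear model with two binary perturbation
#' factors and their interaction, blocking on the per-sample intron-read
#' fraction: `log mu = b0 + b1*x1 + b2*x2 + b3*x1*x2 + g*intron_fraction`
#' (plus a library-size offset). The interaction coefficient measures the
#' deviation of the double-perturbation effect from the sum of the single
#' effects. Coefficients, standard errors and Wald p-values are reported
#' on the log2 scale (the GLM link is natural log; conversion is exact);
#' p-values are BH-adjusted per coefficient across genes.
#'
#' Dispersion is estimated per gene by maximum likelihood with a moderated
#' floor (`sigma >= 1e-4`); genes where the NB fit fails fall back to a
#' Poisson fit at the floor dispersion and are flagged as non-converged
#' rather than dropped.
#'
#' @param counts A [count_matrix()] (samples x genes).
#' @param meta Data frame with columns `sample_id`, `x1`, `x2` (0/1) and
#'   `intron_fraction`, covering every sample. All four design arms must be
#'   present with at least 2 replicates.
#' @param size_factors Optional per-sample normalisation factors; by
#'   default median-of-ratios factors are estimated from the counts.
#' @param use_intron Include the intron-fraction covariate (default TRUE;
#'   automatically dropped with a message when it has no variation).
#' @return A data frame of class `InteractionFit`: gene, beta0..beta3,
#'   gamma, se1..se3, p1..p3, padj1..padj3, dispersion, converged.
#' @export
fit_interaction_model <- function(counts, meta, size_factors = NULL,
                                  use_intron = TRUE) {
  stopifnot(inherits(counts, "CountMatrix"))
  for (f in c("sample_id", "x1", "x2", "intron_fraction")) {
    if (is.null(meta[[f]])) ps_stop(paste0("metadata field missing: ", f), "ps_meta")
  }
  meta <- meta[match(counts$sample_ids, meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) ps_stop("metadata must cover all samples", "ps_meta")
  arms <- table(meta$x1, meta$x2)
  if (!all(dim(arms) == c(2, 2)) || any(arms < 2)) {
    ps_stop("all four design arms need >= 2 replicates", "ps_design")
  }
  if (use_intron && stats::sd(meta$intron_fraction) == 0) {
    message("intron_fraction has no variation; covariate dropped")
    use_intron <- FALSE
  }
  fmla <- if (use_intron) y ~ x1 * x2 + intron_fraction else y ~ x1 * x2
  mm <- stats::model.matrix(fmla[-2], data = meta)
  if (qr(mm)$rank < ncol(mm)) ps_stop("rank-deficient design", "ps_design")

  y_all <- as.matrix(counts$counts)
  if (is.null(size_factors)) size_factors <- estimate_size_factors(y_all)
  off <- log(size_factors)
  ln2 <- log(2)

  fit_one <- function(y) {
    dat <- cbind(meta, y = y)
    fit <- NULL
    converged <- TRUE
    suppressWarnings(
      fit <- tryCatch(
        MASS::glm.nb(stats::update(fmla, . ~ . + offset(off)), data = dat),
        error = function(e) NULL)
    )
    if (is.null(fit) || !isTRUE(fit$converged)) converged <- FALSE
    if (is.null(fit)) {
      fit <- suppressWarnings(
        stats::glm(stats::update(fmla, . ~ . + offset(off)), data = dat,
                   family = stats::poisson()))
      disp <- 1e-4
    } else {
      disp <- max(1 / fit$theta, 1e-4)
    }
    cf <- summary(fit)$coefficients
    pick <- function(term, col) {
      if (term %in% rownames(cf)) cf[term, col] else NA_real_
    }
    c(beta0 = pick("(Intercept)", 1) / ln2,
      beta1 = pick("x1", 1) / ln2,
      beta2 = pick("x2", 1) / ln2,
      beta3 = pick("x1:x2", 1) / ln2,
      gamma = if (use_intron) pick("intron_fraction", 1) / ln2 else NA_real_,
      se1 = pick("x1", 2) / ln2,
      se2 = pick("x2", 2) / ln2,
      se3 = pick("x1:x2", 2) / ln2,
      p1 = pick("x1", 4),
      p2 = pick("x2", 4),
      p3 = pick("x1:x2", 4),
      dispersion = disp,
      converged = as.numeric(converged))
  }
  res <- t(apply(y_all, 2, fit_one))
  out <- data.frame(gene = counts$gene_ids, res, row.names = NULL)
  out$converged <- out$converged > 0
  for (j in 1:3) {
    out[[paste0("padj", j)]] <- stats::p.adjust(out[[paste0("p", j)]],
                                                method = "BH")
  }
  class(out) <- c("InteractionFit", "data.frame")
  out
}

# DESeq-style median-of-ratios size factors (samples x genes matrix)
estimate_size_factors <- function(y) {
  logs <- log(y)
  logs[!is.finite(logs)] <- NA
  ref <- colMeans(logs)  # per-gene log geometric mean over samples
  usable <- is.finite(ref)
  if (!any(usable)) return(rep(1, nrow(y)))
  sf <- apply(logs[, usable, drop = FALSE], 1, function(r) {
    exp(stats::median(r - ref[usable], na.rm = TRUE))
  })
  sf[!is.finite(sf) | sf <= 0] <- 1
  sf
}

#' Classify gene-level perturbation interactions
#'
#' Turns fitted coefficients into a sign triplet (direction of each single
#' perturbation and of the interaction) and an interaction class:
#'
#' * **additive** - the interaction direction is 0 (no change beyond the
#'   sum of single effects),
#' * **synergy** - all three directions agree (the combined perturbation
#'   exceeds the sum of its parts),
#' * **buffering** - the single effects agree but the interaction opposes
#'   them (the combined effect falls short of the sum),
#' * **other** - any remaining nonzero pattern.
#'
#' At **low** stringency only genes differentially expressed for both
#' single perturbations (padj below `fdr_threshold` and |log2fc| above
#' `lfc_threshold`) are classified, and the interaction direction is set by
#' the fold-change filter alone. At **high** stringency every direction
#' (including the interaction) requires both the significance and the
#' fold-change filter.
#'
#' The raw sign triplet is always returned so alternative groupings can be
#' applied downstream.
#'
#' @param fit An `InteractionFit` from [fit_interaction_model()].
#' @param stringency `"low"` or `"high"`.
#' @param lfc_threshold Minimum |log2 fold change| (default 0.2, exclusive).
#' @param fdr_threshold Adjusted-p threshold (default 0.1, exclusive).
#' @return A data frame of class `InteractionCall`: gene, dir1, dir2,
#'   dirInt (`+`/`-`/`0`), class, eligible, stringency.
#' @export
classify_interactions <- function(fit, stringency = c("low", "high"),
                                  lfc_threshold = 0.2, fdr_threshold = 0.1) {
  stringency <- match.arg(stringency)
  if (lfc_threshold <= 0 || fdr_threshold <= 0) {
    ps_stop("thresholds must be positive", "ps_arg")
  }
  stopifnot(inherits(fit, "InteractionFit"))
  sig_dir <- function(b, padj) {
    ifelse(!is.na(padj) & padj < fdr_threshold & abs(b) > lfc_threshold,
           sign(b), 0)
  }
  lfc_dir <- function(b) ifelse(abs(b) > lfc_threshold, sign(b), 0)

  if (stringency == "low") {
    eligible <- sig_dir(fit$beta1, fit$padj1) != 0 &
      sig_dir(fit$beta2, fit$padj2) != 0
    d1 <- ifelse(eligible, sign(fit$beta1), NA)
    d2 <- ifelse(eligible, sign(fit$beta2), NA)
    d3 <- ifelse(eligible, lfc_dir(fit$beta3), NA)
  } else {
    eligible <- rep(TRUE, nrow(fit))
    d1 <- sig_dir(fit$beta1, fit$padj1)
    d2 <- sig_dir(fit$beta2, fit$padj2)
    d3 <- sig_dir(fit$beta3, fit$padj3)
  }
  cls <- ifelse(is.na(d3), NA_character_,
         ifelse(d3 == 0, "additive",
         ifelse(d1 == d2 & d1 == d3 & d1 != 0, "synergy",
         ifelse(d1 == d2 & d1 != 0 & d3 == -d1, "buffering", "other"))))
  out <- data.frame(gene = fit$gene,
                    dir1 = ifelse(is.na(d1), NA_character_, dir_symbol(d1)),
                    dir2 = ifelse(is.na(d2), NA_character_, dir_symbol(d2)),
                    dirInt = ifelse(is.na(d3), NA_character_, dir_symbol(d3)),
                    class = cls, eligible = eligible,
                    stringency = stringency, row.names = NULL)
  class(out) <- c("InteractionCall", "data.frame")
  out
}
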
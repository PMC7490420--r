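# Simulation-based horizontal-pleiotropy detection: global residual-sum-of-
# squares test, per-variant outlier test, distortion test, and the mr_presso()
# front end.  All null distributions are parametric simulations around the
# leave-one-out IVW fits; empirical p-values use add-one smoothing so they lie
# in (0, 1].

# Leave-one-out plain-IVW slopes, closed form via totals.
.loo_slopes <- function(gamma, Gamma, w) {
  sxy <- sum(w * gamma * Gamma)
  sxx <- sum(w * gamma^2)
  (sxy - w * gamma * Gamma) / (sxx - w * gamma^2)
}

# Shared simulation engine: observed global RSS and per-variant squared
# residuals, plus their simulated counterparts (n_snps x n_sim matrices).
.presso_sim <- function(data, n_sim) {
  g <- data$gamma; G <- data$Gamma
  sx <- data$se_x; sy <- data$se_y
  n <- length(g)
  w <- 1 / sy^2
  b_loo <- .loo_slopes(g, G, w)
  res_obs <- w * (G - b_loo * g)^2
  rss_obs <- sum(res_obs)

  Gs <- matrix(rnorm(n * n_sim, mean = g, sd = sx), nrow = n)
  Os <- matrix(rnorm(n * n_sim, mean = b_loo * g, sd = sy), nrow = n)
  A <- w * Gs^2
  B <- w * Gs * Os
  sxx_s <- colSums(A)
  sxy_s <- colSums(B)
  b_s <- (rep(sxy_s, each = n) - B) / (rep(sxx_s, each = n) - A)
  res_s <- w * (Os - b_s * Gs)^2
  list(rss_obs = rss_obs, res_obs = res_obs,
       rss_sim = colSums(res_s), res_sim = res_s)
}

#' MR-PRESSO global heterogeneity test
#'
#' The observed statistic is the residual sum of squares of each variant
#' against its leave-one-out plain-IVW prediction, weighted by `1/se_y^2`.
#' The null distribution is simulated by redrawing every variant's effects
#' from normal distributions centred on the leave-one-out predictions and
#' recomputing the statistic.
#'
#' @param data a [harmonized_instruments()] set with at least 4 variants.
#' @param n_sim simulation replicates, default 1000.
#' @param seed optional integer RNG seed.
#' @return List with `rss_obs` and `p_global` (add-one-smoothed empirical p).
#' @export
mrpresso_global <- function(data, n_sim = 1000, seed = NULL) {
  data <- .check_hset(data)
  if (nrow(data) < 4L) stop("MR-PRESSO needs at least 4 variants")
  if (!is.null(seed)) set.seed(seed)
  sim <- .presso_sim(data, n_sim)
  list(rss_obs = sim$rss_obs,
       p_global = (1 + sum(sim$rss_sim >= sim$rss_obs)) / (n_sim + 1))
}

#' MR-PRESSO per-variant outlier test
#'
#' Each variant's observed squared residual is compared with its simulated
#' distribution; raw empirical p-values are Bonferroni-adjusted by the number
#' of variants and outliers are those with adjusted p below `alpha`.
#'
#' @inheritParams mrpresso_global
#' @param alpha outlier significance level on the adjusted p-value,
#'   default 0.05.
#' @return List with `p_raw`, `p_adjusted` (named by rsid) and `outliers`
#'   (character vector of flagged rsids).
#' @export
mrpresso_outliers <- function(data, n_sim = 1000, seed = NULL, alpha = 0.05) {
  data <- .check_hset(data)
  n <- nrow(data)
  if (n < 4L) stop("MR-PRESSO needs at least 4 variants")
  if (!is.null(seed)) set.seed(seed)
  sim <- .presso_sim(data, n_sim)
  p_raw <- (1 + rowSums(sim$res_sim >= sim$res_obs)) / (n_sim + 1)
  p_adj <- pmin(1, p_raw * n)
  names(p_raw) <- names(p_adj) <- data$rsid
  list(p_raw = p_raw, p_adjusted = p_adj,
       outliers = data$rsid[p_adj < alpha])
}

#' MR-PRESSO distortion test
#'
#' Compares the raw plain-IVW estimate with the outlier-corrected one
#' (plain IVW on the non-outlier variants).  The observed distortion is
#' `100 * (beta_corrected - beta_raw) / |beta_corrected|`; the null removes
#' the same number of variants uniformly at random and recomputes it, giving
#' a two-sided empirical p-value.
#'
#' @inheritParams mrpresso_global
#' @param outliers character vector of outlier rsids (from
#'   [mrpresso_outliers()]); must be non-empty and leave at least 3 variants.
#' @param n_sim_distortion null replicates, default 1000.
#' @return List with `distortion_pct`, `pvalue`, `corrected` (an
#'   `mr_estimate`) and `raw` (an `mr_estimate`).
#' @export
mrpresso_distortion <- function(data, outliers, n_sim_distortion = 1000,
                                seed = NULL) {
  data <- .check_hset(data)
  n <- nrow(data)
  if (length(outliers) < 1L) stop("distortion test needs at least one outlier")
  is_out <- data$rsid %in% outliers
  if (sum(!is_out) < 3L)
    stop("distortion test needs at least 3 non-outlier variants")
  if (!is.null(seed)) set.seed(seed)
  raw <- mr_ivw(data, robust = FALSE, scale_se = n >= 2L)
  corrected <- mr_ivw(.subset_hset(data, !is_out), robust = FALSE)
  d_obs <- 100 * (corrected$beta - raw$beta) / abs(corrected$beta)
  n_out <- sum(is_out)
  w <- 1 / data$se_y^2
  wg2 <- w * data$gamma^2
  wgG <- w * data$gamma * data$Gamma
  d_sim <- vapply(seq_len(n_sim_distortion), function(i) {
    drop_idx <- sample.int(n, n_out)
    b <- sum(wgG[-drop_idx]) / sum(wg2[-drop_idx])
    100 * (b - raw$beta) / abs(b)
  }, numeric(1))
  list(distortion_pct = d_obs,
       pvalue = (1 + sum(abs(d_sim) >= abs(d_obs))) / (n_sim_distortion + 1),
       corrected = corrected, raw = raw)
}

#' MR-PRESSO analysis: global, outlier and distortion tests
#'
#' Runs the global heterogeneity test and the per-variant outlier test on one
#' shared simulation set, then, when outliers are found and at least three
#' variants remain, the outlier-corrected re-estimate and distortion test.
#' Plain (non-robust) IVW is used throughout, matching the procedure's
#' definition; outlier removal is single pass.
#'
#' @inheritParams mrpresso_outliers
#' @param n_sim_distortion null replicates for the distortion test.
#' @return An object of class `mr_presso`: `rss_obs`, `p_global`, `p_raw`,
#'   `p_adjusted`, `outliers`, `raw_estimate`, and — when applicable —
#'   `corrected_estimate`, `distortion_pct`, `distortion_pvalue`; plus
#'   `n_sim`, `seed` provenance and `skipped_reason` when the correction was
#'   not possible.
#' @export
mr_presso <- function(data, n_sim = 1000, seed = NULL, alpha = 0.05,
                      n_sim_distortion = 1000) {
  data <- .check_hset(data)
  n <- nrow(data)
  if (n < 4L) stop("MR-PRESSO needs at least 4 variants")
  if (!is.null(seed)) set.seed(seed)
  sim <- .presso_sim(data, n_sim)
  p_global <- (1 + sum(sim$rss_sim >= sim$rss_obs)) / (n_sim + 1)
  p_raw <- (1 + rowSums(sim$res_sim >= sim$res_obs)) / (n_sim + 1)
  p_adj <- pmin(1, p_raw * n)
  names(p_raw) <- names(p_adj) <- data$rsid
  outliers <- data$rsid[p_adj < alpha]
  out <- list(rss_obs = sim$rss_obs, p_global = p_global, p_raw = p_raw,
              p_adjusted = p_adj, outliers = outliers,
              raw_estimate = mr_ivw(data, robust = FALSE),
              corrected_estimate = NULL, distortion_pct = NULL,
              distortion_pvalue = NULL, skipped_reason = NULL,
              n_sim = n_sim, n_sim_distortion = n_sim_distortion,
              alpha = alpha, seed = seed)
  if (length(outliers) == 0L) {
    out$skipped_reason <- "no outliers detected"
  } else if (n - length(outliers) < 3L) {
    out$skipped_reason <- "fewer than 3 non-outlier variants remain"
  } else {
    dist <- mrpresso_distortion(data, outliers,
                                n_sim_distortion = n_sim_distortion)
    out$corrected_estimate <- dist$corrected
    out$distortion_pct <- dist$distortion_pct
    out$distortion_pvalue <- dist$pvalue
  }
  structure(out, class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO (n_sim = %d): RSS = %.3g, global p = %.4g\n",
              x$n_sim, x$rss_obs, x$p_global))
  if (length(x$outliers)) {
    cat("Outliers:", paste(x$outliers, collapse = ", "), "\n")
    cat("Raw:       "); print(x$raw_estimate)
    if (!is.null(x$corrected_estimate)) {
      cat("Corrected: "); print(x$corrected_estimate)
      cat(sprintf("Distortion = %.2f%%, p = %.4g\n", x$distortion_pct,
                  x$distortion_pvalue))
    } else {
      cat("Correction skipped:", x$skipped_reason, "\n")
    }
  } else {
    cat("No outliers detected.\n")
  }
  invisible(x)
}
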
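# Causal-effect estimators for a harmonized instrument set: Wald ratio,
# IVW (plain/robust), MR-Egger (plain/robust), weighted median, Cochran's Q,
# leave-one-out, and the mr_fit() front end.

.mr_estimate <- function(method, beta, se, n_snps) {
  z <- beta / se
  ci_low <- beta - .z95 * se
  ci_high <- beta + .z95 * se
  structure(list(method = method, n_snps = n_snps, beta = beta, se = se,
                 ci_low = ci_low, ci_high = ci_high,
                 pvalue = 2 * pnorm(-abs(z)),
                 or = exp(beta), or_low = exp(ci_low), or_high = exp(ci_high)),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (%d variants): beta = %.4f (se %.4f), OR = %.3f (95%% CI %.3f, %.3f), p = %.3g\n",
              x$method, x$n_snps, x$beta, x$se, x$or, x$or_low, x$or_high,
              x$pvalue))
  invisible(x)
}

.check_hset <- function(data) {
  stopifnot(inherits(data, "harmonized_instruments"))
  data
}

#' Single-variant Wald ratio
#'
#' The causal estimate from one instrument: the variant-outcome effect divided
#' by the variant-exposure effect, with first-order (delta-method) standard
#' error `se_y / |gamma|`.
#'
#' @param gamma,se_x variant-exposure effect and standard error.
#' @param Gamma,se_y variant-outcome effect and standard error.
#' @return List with `ratio` and `se`.
#' @export
mr_wald_ratio <- function(gamma, se_x, Gamma, se_y) {
  if (any(gamma == 0)) stop("Wald ratio undefined for gamma = 0")
  list(ratio = Gamma / gamma, se = se_y / abs(gamma))
}

# Robust (MM, Tukey bisquare) fit of precision-scaled variables; returns
# coefficients and standard errors with the multiplicative dispersion floored
# at 1 (an estimated residual scale below 1 never shrinks the errors).
.robust_wls <- function(X, y, scale_se) {
  fit <- tryCatch(
    MASS::rlm(X, y, method = "MM", psi = MASS::psi.bisquare, c = 4.685,
              maxit = 200, acc = 1e-8),
    error = function(e) NULL)
  if (is.null(fit) || !isTRUE(fit$converged)) return(NULL)
  sf <- summary(fit)$coefficients
  se <- sf[, 2L]
  if (scale_se) se <- se / min(1, fit$s)
  list(coef = coef(fit), se = se)
}

#' Inverse-variance-weighted causal estimate
#'
#' Weighted zero-intercept regression of the variant-outcome effects on the
#' variant-exposure effects with weights `1/se_y^2`.  The plain estimator has
#' the closed form `sum(gamma*Gamma/se_y^2) / sum(gamma^2/se_y^2)` with
#' unscaled standard error `sqrt(1/sum(gamma^2/se_y^2))`; with `scale_se` the
#' standard error is multiplied by `max(1, sqrt(RSS/(n-1)))` (multiplicative
#' random-effects model that never shrinks it).  The robust variant refits the
#' same regression by MM-estimation with Tukey's bisquare (tuning constant
#' 4.685) on the precision-scaled variables `Gamma/se_y ~ gamma/se_y`; if the
#' robust fit does not converge it falls back to the plain fit with a warning.
#' P-values and confidence intervals use normal quantiles throughout.
#'
#' @param data a [harmonized_instruments()] set.
#' @param robust use MM-estimation, default `FALSE`.
#' @param scale_se apply the multiplicative random-effects scaling (floor 1),
#'   default `TRUE`; requires at least 2 variants.
#' @return An `mr_estimate`.
#' @export
mr_ivw <- function(data, robust = FALSE, scale_se = TRUE) {
  data <- .check_hset(data)
  n <- nrow(data)
  if (robust && n < 3L)
    stop("robust IVW needs at least 3 variants")
  if (scale_se && n < 2L)
    stop("IVW standard-error scaling needs at least 2 variants")
  if (n < 1L) stop("IVW needs at least 1 variant")
  w <- 1 / data$se_y^2
  sxx <- sum(w * data$gamma^2)
  beta <- sum(w * data$gamma * data$Gamma) / sxx
  se <- sqrt(1 / sxx)
  method <- if (robust) "ivw_robust" else "ivw"
  if (robust) {
    rf <- .robust_wls(cbind(x = data$gamma / data$se_y), data$Gamma / data$se_y,
                      scale_se)
    if (is.null(rf)) {
      warning("robust IVW fit did not converge; falling back to plain IVW")
    } else {
      est <- .mr_estimate(method, unname(rf$coef[1L]), unname(rf$se[1L]), n)
      return(est)
    }
  }
  if (scale_se) {
    rss <- sum(w * (data$Gamma - beta * data$gamma)^2)
    se <- se * max(1, sqrt(rss / (n - 1)))
  }
  .mr_estimate(method, beta, se, n)
}

#' MR-Egger regression
#'
#' Weighted regression `Gamma = theta0 + beta * gamma` with weights
#' `1/se_y^2`: unlike IVW the intercept is free, and a non-null intercept
#' estimates the average directional pleiotropic effect.  Requires exposure
#' effects oriented positive (done by [harmonize()]).  The robust variant uses
#' MM-estimation as in [mr_ivw()]; standard errors are scaled multiplicatively
#' with floor 1, and the intercept is reported both raw and exponentiated.
#'
#' @inheritParams mr_ivw
#' @return An `mr_egger_fit` with components `slope` (an `mr_estimate`) and
#'   `intercept` (`estimate`, `se`, `ci_low`, `ci_high`, `pvalue`, `or`).
#' @export
mr_egger <- function(data, robust = FALSE, scale_se = TRUE) {
  data <- .check_hset(data)
  n <- nrow(data)
  if (n < 3L) stop("MR-Egger needs at least 3 variants")
  if (length(unique(data$gamma)) == 1L)
    stop("MR-Egger is unidentified when all exposure effects are equal")
  X <- cbind(intercept = 1 / data$se_y, x = data$gamma / data$se_y)
  y <- data$Gamma / data$se_y
  method <- if (robust) "egger_robust" else "egger"
  cf <- se <- NULL
  if (robust) {
    rf <- .robust_wls(X, y, scale_se)
    if (is.null(rf))
      warning("robust MR-Egger fit did not converge; falling back to plain fit")
    else { cf <- rf$coef; se <- rf$se }
  }
  if (is.null(cf)) {
    xtx <- crossprod(X)
    cf <- drop(solve(xtx, crossprod(X, y)))
    vc <- solve(xtx)
    se <- sqrt(diag(vc))
    if (scale_se) {
      rss <- sum((y - drop(X %*% cf))^2)
      se <- se * max(1, sqrt(rss / (n - 2)))
    }
  }
  slope <- .mr_estimate(method, unname(cf[2L]), unname(se[2L]), n)
  i_est <- unname(cf[1L]); i_se <- unname(se[1L])
  intercept <- list(estimate = i_est, se = i_se,
                    ci_low = i_est - .z95 * i_se, ci_high = i_est + .z95 * i_se,
                    pvalue = 2 * pnorm(-abs(i_est / i_se)), or = exp(i_est))
  structure(list(slope = slope, intercept = intercept),
            class = "mr_egger_fit")
}

#' @export
print.mr_egger_fit <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept = %.5f (se %.5f, exp = %.3f), p = %.3g\n",
              x$intercept$estimate, x$intercept$se, x$intercept$or,
              x$intercept$pvalue))
  invisible(x)
}

# Weighted-median point estimate: cumulative-midpoint interpolation of the
# sorted per-variant ratios at probability 0.5, clamped at the extremes.
.weighted_median_point <- function(ratios, weights) {
  o <- order(ratios)
  b <- ratios[o]
  w <- weights[o] / sum(weights)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1L]) return(b[1L])
  k <- length(b)
  if (0.5 >= p[k]) return(b[k])
  approx(p, b, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' Consistent when at least half of the instrument weight comes from valid
#' variants.  Per-variant ratios `Gamma/gamma` are combined with weights
#' `gamma^2/se_y^2`; the estimate interpolates the weighted cumulative
#' distribution of sorted ratios at 0.5.  The standard error is the standard
#' deviation of the estimate over `n_boot` parametric-bootstrap replicates
#' drawing `gamma* ~ N(gamma, se_x^2)` and `Gamma* ~ N(Gamma, se_y^2)`.
#'
#' @inheritParams mr_ivw
#' @param n_boot bootstrap replicates for the standard error, default 1000.
#' @param seed optional integer; when supplied the RNG is seeded so the
#'   bootstrap is reproducible.
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(data, n_boot = 1000, seed = NULL) {
  data <- .check_hset(data)
  n <- nrow(data)
  if (n < 3L) stop("weighted median needs at least 3 variants")
  if (any(data$gamma == 0)) stop("weighted median undefined for gamma = 0")
  w <- data$gamma^2 / data$se_y^2
  est <- .weighted_median_point(data$Gamma / data$gamma, w)
  if (!is.null(seed)) set.seed(seed)
  G <- matrix(rnorm(n * n_boot, mean = data$gamma, sd = data$se_x), nrow = n)
  O <- matrix(rnorm(n * n_boot, mean = data$Gamma, sd = data$se_y), nrow = n)
  boot <- vapply(seq_len(n_boot), function(i) {
    g <- G[, i]
    if (any(g == 0)) return(NA_real_)
    .weighted_median_point(O[, i] / g, g^2 / data$se_y^2)
  }, numeric(1))
  se <- sd(boot, na.rm = TRUE)
  .mr_estimate("weighted_median", est, se, n)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum((Gamma - beta*gamma)^2 / se_y^2)` with `n - 1` degrees of freedom
#' (one causal parameter estimated) and an upper-tail chi-square p-value.
#'
#' @inheritParams mr_ivw
#' @param beta causal estimate the residuals are taken against; defaults to
#'   the plain IVW estimate.
#' @return List with `Q`, `df`, `pvalue`.
#' @export
mr_cochran_q <- function(data, beta = NULL) {
  data <- .check_hset(data)
  n <- nrow(data)
  if (n < 2L) stop("Cochran's Q needs at least 2 variants")
  if (is.null(beta)) {
    w <- 1 / data$se_y^2
    beta <- sum(w * data$gamma * data$Gamma) / sum(w * data$gamma^2)
  }
  Q <- sum((data$Gamma - beta * data$gamma)^2 / data$se_y^2)
  df <- n - 1L
  list(Q = Q, df = df, pvalue = pchisq(Q, df, lower.tail = FALSE))
}

# Dispatch a single estimation method; Egger results are reduced to the slope
# with the intercept carried alongside.
.fit_one <- function(data, method, n_boot = 1000, seed = NULL, scale_se = TRUE) {
  switch(method,
    ivw = mr_ivw(data, robust = FALSE, scale_se = scale_se),
    ivw_robust = mr_ivw(data, robust = TRUE, scale_se = scale_se),
    egger = mr_egger(data, robust = FALSE, scale_se = scale_se),
    egger_robust = mr_egger(data, robust = TRUE, scale_se = scale_se),
    weighted_median = mr_weighted_median(data, n_boot = n_boot, seed = seed),
    stop("unknown method: ", method))
}

.point_estimate <- function(fit) if (inherits(fit, "mr_egger_fit")) fit$slope else fit

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the causal effect with each instrument omitted in turn, plus
#' the all-variant estimate, to reveal single influential variants.
#'
#' @inheritParams mr_ivw
#' @param method estimation method, default `"ivw_robust"`.
#' @param n_boot,seed passed to [mr_weighted_median()] when used.
#' @return An `mr_loo` data frame with one row per omitted variant and a final
#'   `"(all)"` row, carrying beta/OR and 95% CI columns.
#' @export
mr_leave_one_out <- function(data, method = "ivw_robust", n_boot = 1000,
                             seed = NULL, scale_se = TRUE) {
  data <- .check_hset(data)
  n <- nrow(data)
  if (n < 4L) stop("leave-one-out needs at least 4 variants")
  one_row <- function(fit, label) {
    e <- .point_estimate(fit)
    data.frame(omitted = label, n_snps = e$n_snps, beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, pvalue = e$pvalue,
               or = e$or, or_low = e$or_low, or_high = e$or_high,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(n), function(i) {
    fit <- tryCatch(
      .fit_one(.subset_hset(data, -i), method, n_boot, seed, scale_se),
      error = function(e)
        stop("leave-one-out failed omitting ", data$rsid[i], ": ",
             conditionMessage(e), call. = FALSE))
    one_row(fit, data$rsid[i])
  })
  rows <- c(rows, list(one_row(.fit_one(data, method, n_boot, seed, scale_se),
                               "(all)")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("mr_loo", "data.frame"), method = method)
}

.subset_hset <- function(data, idx) {
  out <- as.data.frame(data)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(data),
            exposure_id = attr(data, "exposure_id"),
            outcome_id = attr(data, "outcome_id"))
}

#' Fit the full battery of Mendelian-randomization estimators
#'
#' The front end of the genetic arm: takes a harmonized instrument set and
#' fits the requested estimators (robust IVW first by convention — the
#' headline method — with plain IVW, robust/plain MR-Egger and the weighted
#' median as sensitivity analyses), plus Cochran's Q against the plain IVW
#' estimate.
#'
#' @param data a [harmonized_instruments()] set.
#' @param methods character vector drawn from `"ivw"`, `"ivw_robust"`,
#'   `"egger"`, `"egger_robust"`, `"weighted_median"`.  The first is treated
#'   as the primary method by `coef()`, `plot()` and `residuals()`.
#' @param n_boot bootstrap replicates for the weighted median.
#' @param seed integer seed recorded in the fit and used for the bootstrap.
#' @param scale_se multiplicative random-effects scaling of standard errors.
#' @return An object of class `mr_fit` with components `estimates` (named list
#'   of `mr_estimate`), `egger` (named list of intercept summaries), `q`
#'   (Cochran's Q), `data`, `n_snps`, `seed`.
#' @seealso [mr_leave_one_out()], [mr_presso()], [summary.mr_fit()]
#' @examples
#' hs <- harmonized_instruments(
#'   rsid = paste0("rs", 1:6), gamma = c(.08, .1, .12, .09, .11, .1),
#'   se_x = .01, Gamma = c(.018, .024, .028, .020, .026, .023), se_y = .004)
#' fit <- mr_fit(hs, seed = 1)
#' summary(fit)
#' @export
mr_fit <- function(data,
                   methods = c("ivw_robust", "ivw", "egger_robust", "egger",
                               "weighted_median"),
                   n_boot = 1000, seed = NULL, scale_se = TRUE) {
  data <- .check_hset(data)
  methods <- match.arg(methods, several.ok = TRUE)
  fits <- lapply(methods, function(m)
    .fit_one(data, m, n_boot = n_boot, seed = seed, scale_se = scale_se))
  names(fits) <- methods
  egger <- lapply(fits[grepl("^egger", names(fits))], `[[`, "intercept")
  estimates <- lapply(fits, .point_estimate)
  q <- if (nrow(data) >= 2L) mr_cochran_q(data) else NULL
  structure(list(estimates = estimates, egger = egger, q = q, data = data,
                 n_snps = nrow(data), seed = seed, n_boot = n_boot,
                 methods = methods, call = match.call()),
            class = "mr_fit")
}

.mr_fit_table <- function(x) {
  rows <- lapply(x$estimates, function(e)
    data.frame(method = e$method, n_snps = e$n_snps, beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, pvalue = e$pvalue,
               or = e$or, or_low = e$or_low, or_high = e$or_high,
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("Mendelian-randomization fit: %s -> %s (%d instruments)\n",
              attr(x$data, "exposure_id"), attr(x$data, "outcome_id"),
              x$n_snps))
  tab <- .mr_fit_table(x)
  tab$or_ci <- sprintf("%.3f (%.3f, %.3f)", tab$or, tab$or_low, tab$or_high)
  print(data.frame(method = tab$method, `OR (95% CI)` = tab$or_ci,
                   p = signif(tab$pvalue, 3), check.names = FALSE),
        row.names = FALSE)
  invisible(x)
}

#' Summarize a Mendelian-randomization fit
#'
#' @param object an [mr_fit()] object.
#' @param ... unused.
#' @return A `summary.mr_fit` with the per-method estimate table, Egger
#'   intercepts and Cochran's Q.
#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(table = .mr_fit_table(object), egger = object$egger,
                 q = object$q, n_snps = object$n_snps,
                 exposure_id = attr(object$data, "exposure_id"),
                 outcome_id = attr(object$data, "outcome_id")),
            class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  cat(sprintf("Two-sample MR: %s -> %s, %d instruments\n\n",
              x$exposure_id, x$outcome_id, x$n_snps))
  tab <- x$table
  tab$beta <- sprintf("%.4f", tab$beta)
  tab$se <- sprintf("%.4f", tab$se)
  tab$or_ci <- sprintf("%.3f (%.3f, %.3f)", tab$or, tab$or_low, tab$or_high)
  print(data.frame(method = tab$method, beta = tab$beta, se = tab$se,
                   `OR (95% CI)` = tab$or_ci, p = signif(tab$pvalue, 3),
                   check.names = FALSE), row.names = FALSE)
  for (nm in names(x$egger)) {
    ic <- x$egger[[nm]]
    cat(sprintf("\n%s intercept: %.5f (exp %.3f), p = %.3g",
                nm, ic$estimate, ic$or, ic$pvalue))
  }
  if (!is.null(x$q))
    cat(sprintf("\nCochran's Q = %.2f, df = %d, p = %.3g\n",
                x$q$Q, x$q$df, x$q$pvalue))
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  vapply(object$estimates, `[[`, numeric(1), "beta")
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  tab <- .mr_fit_table(object)
  out <- cbind(tab$beta - z * tab$se, tab$beta + z * tab$se)
  dimnames(out) <- list(tab$method,
                        sprintf("%g %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
residuals.mr_fit <- function(object, method = NULL, ...) {
  method <- if (is.null(method)) object$methods[1L] else method
  beta <- object$estimates[[method]]$beta
  d <- object$data
  setNames((d$Gamma - beta * d$gamma) / d$se_y, d$rsid)
}

#' Scatter plot of instrument effects with fitted slopes
#'
#' Plots per-variant outcome effects against exposure effects with 95%
#' confidence bars and one fitted line per estimator (Egger lines keep their
#' intercept; others pass through the origin).
#'
#' @param x an [mr_fit()] object.
#' @param ... passed to [plot()].
#' @export
plot.mr_fit <- function(x, ...) {
  d <- x$data
  xlim <- range(0, d$gamma - .z95 * d$se_x, d$gamma + .z95 * d$se_x)
  ylim <- range(0, d$Gamma - .z95 * d$se_y, d$Gamma + .z95 * d$se_y)
  plot(d$gamma, d$Gamma, xlim = xlim, ylim = ylim, pch = 19,
       xlab = sprintf("effect on %s", attr(d, "exposure_id")),
       ylab = sprintf("effect on %s", attr(d, "outcome_id")), ...)
  graphics::segments(d$gamma - .z95 * d$se_x, d$Gamma,
                     d$gamma + .z95 * d$se_x, d$Gamma, col = "grey60")
  graphics::segments(d$gamma, d$Gamma - .z95 * d$se_y,
                     d$gamma, d$Gamma + .z95 * d$se_y, col = "grey60")
  for (i in seq_along(x$estimates)) {
    e <- x$estimates[[i]]
    icpt <- if (e$method %in% names(x$egger)) x$egger[[e$method]]$estimate else 0
    graphics::abline(icpt, e$beta, lty = i)
  }
  graphics::legend("topleft", legend = names(x$estimates),
                   lty = seq_along(x$estimates), bty = "n", cex = 0.8)
  invisible(x)
}
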
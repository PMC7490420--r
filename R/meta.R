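# Observational arm: log-scale effect handling, DerSimonian-Laird
# random-effects pooling, heterogeneity, subgroup and leave-one-study-out
# analyses, Begg and Egger publication-bias tests.

#' Convert a study-level risk estimate to the log scale
#'
#' `y = log(estimate)`; the standard error is recovered from the reported 95%
#' interval as `(log(ci_high) - log(ci_low)) / (2 * 1.959964)`.  Hazard ratios
#' are pooled as-is with relative risks; odds ratios can optionally be
#' converted to relative risks via `RR = OR / (1 - p0 + p0 * OR)` when a
#' baseline risk `p0` is supplied (conversion applied to the estimate and both
#' interval bounds).
#'
#' @param estimate,ci_low,ci_high positive effect estimate and 95% bounds,
#'   with `ci_low < estimate < ci_high` (vectorized).
#' @param measure `"RR"`, `"OR"` or `"HR"` (recycled).
#' @param baseline_risk optional baseline risk in (0,1) for OR-to-RR
#'   conversion.
#' @param convert_or_to_rr apply the conversion (default `FALSE`; requires
#'   `baseline_risk`).
#' @return Data frame with log effect `y` and variance `v`.
#' @export
to_log_effect <- function(estimate, ci_low, ci_high, measure = "RR",
                          baseline_risk = NULL, convert_or_to_rr = FALSE) {
  measure <- rep(toupper(measure), length.out = length(estimate))
  if (!all(measure %in% c("RR", "OR", "HR")))
    stop("measure must be RR, OR or HR")
  if (any(estimate <= 0 | ci_low <= 0 | ci_high <= 0))
    stop("effect estimates and interval bounds must be positive")
  if (any(ci_low >= estimate | ci_high <= estimate))
    stop("need ci_low < estimate < ci_high")
  if (convert_or_to_rr) {
    if (is.null(baseline_risk)) stop("OR-to-RR conversion needs baseline_risk")
    p0 <- rep(baseline_risk, length.out = length(estimate))
    conv <- measure == "OR" & !is.na(p0)
    or_to_rr <- function(or, p0) or / (1 - p0 + p0 * or)
    estimate[conv] <- or_to_rr(estimate[conv], p0[conv])
    ci_low[conv] <- or_to_rr(ci_low[conv], p0[conv])
    ci_high[conv] <- or_to_rr(ci_high[conv], p0[conv])
  }
  se <- (log(ci_high) - log(ci_low)) / (2 * .z95)
  data.frame(y = log(estimate), v = se^2)
}

# y/v extraction for a study table (study_id, measure, estimate, ci_low,
# ci_high, optional baseline_risk).
.meta_yv <- function(records, convert_or_to_rr = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("study_id", "estimate", "ci_low", "ci_high") %in% names(records)))
  measure <- if ("measure" %in% names(records)) records$measure else "RR"
  p0 <- if ("baseline_risk" %in% names(records)) records$baseline_risk else NULL
  yv <- to_log_effect(records$estimate, records$ci_low, records$ci_high,
                      measure = measure, baseline_risk = p0,
                      convert_or_to_rr = convert_or_to_rr)
  yv$study_id <- as.character(records$study_id)
  yv
}

#' DerSimonian-Laird random-effects pooling
#'
#' Moment-based random-effects meta-analysis of log-scale effects: with fixed
#' weights `w = 1/v`, `Q = sum(w * (y - mu_F)^2)` around the fixed-effect mean,
#' `tau2 = max(0, (Q - (k-1)) / (S1 - S2/S1))` with `S1 = sum(w)`,
#' `S2 = sum(w^2)`, and the pooled estimate uses random-effects weights
#' `1/(v + tau2)`.  `I2 = max(0, (Q - df)/Q) * 100` (0 when `Q = 0`).  With a
#' single study the study itself is returned, `tau2 = 0` and `Q` absent.
#'
#' @param y log-scale effect estimates.
#' @param v their variances.
#' @param slab optional study labels.
#' @return An object of class `meta_dl`: `k`, `mu` (pooled log effect), `se`,
#'   `ci_low`/`ci_high` (log scale), `rr`/`rr_low`/`rr_high` (ratio scale),
#'   `pvalue`, `Q`, `df`, `p_Q`, `i2_percent`, `tau2`, `mu_fixed`, and the
#'   inputs `yi`, `vi`, `slab`.
#' @examples
#' fit <- meta_dl(y = c(0, 2), v = c(1, 1))
#' fit$Q        # 2
#' fit$tau2     # 1
#' fit$i2_percent  # 50
#' @export
meta_dl <- function(y, v, slab = NULL) {
  k <- length(y)
  if (k == 0L) stop("meta-analysis needs at least one study")
  if (length(v) != k) stop("y and v lengths differ")
  if (any(v <= 0)) stop("variances must be positive")
  if (is.null(slab)) slab <- sprintf("study_%02d", seq_len(k))
  if (k == 1L) {
    mu <- y; se <- sqrt(v); Q <- NA_real_; p_Q <- NA_real_
    i2 <- NA_real_; tau2 <- 0; mu_f <- y; df <- NA_integer_
  } else {
    w <- 1 / v
    s1 <- sum(w); s2 <- sum(w^2)
    mu_f <- sum(w * y) / s1
    Q <- sum(w * (y - mu_f)^2)
    df <- k - 1L
    tau2 <- max(0, (Q - df) / (s1 - s2 / s1))
    ws <- 1 / (v + tau2)
    mu <- sum(ws * y) / sum(ws)
    se <- sqrt(1 / sum(ws))
    p_Q <- pchisq(Q, df, lower.tail = FALSE)
    i2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  }
  structure(list(k = k, mu = mu, se = se,
                 ci_low = mu - .z95 * se, ci_high = mu + .z95 * se,
                 rr = exp(mu), rr_low = exp(mu - .z95 * se),
                 rr_high = exp(mu + .z95 * se),
                 pvalue = 2 * pnorm(-abs(mu / se)),
                 Q = Q, df = df, p_Q = p_Q, i2_percent = i2, tau2 = tau2,
                 mu_fixed = mu_f, yi = y, vi = v, slab = slab),
            class = "meta_dl")
}

#' Pool a study table with the DerSimonian-Laird model
#'
#' Convenience wrapper: converts a study table (columns `study_id`, `measure`,
#' `estimate`, `ci_low`, `ci_high`, optional `baseline_risk` and label
#' columns) to log effects with [to_log_effect()] and pools with [meta_dl()].
#'
#' @param records study table.
#' @param convert_or_to_rr passed to [to_log_effect()].
#' @return A `meta_dl` fit.
#' @export
meta_dl_records <- function(records, convert_or_to_rr = FALSE) {
  yv <- .meta_yv(records, convert_or_to_rr)
  meta_dl(yv$y, yv$v, slab = yv$study_id)
}

#' @export
print.meta_dl <- function(x, ...) {
  cat(sprintf("Random-effects (DL) pooling of %d studies\n", x$k))
  cat(sprintf("  RR = %.3f (95%% CI %.3f, %.3f), p = %.3g\n",
              x$rr, x$rr_low, x$rr_high, x$pvalue))
  if (!is.na(x$Q))
    cat(sprintf("  Q = %.2f (df %d, p = %.3g), I2 = %.1f%%, tau2 = %.4g\n",
                x$Q, x$df, x$p_Q, x$i2_percent, x$tau2))
  invisible(x)
}

#' @export
summary.meta_dl <- function(object, ...) {
  per_study <- data.frame(
    study_id = object$slab, y = object$yi, se = sqrt(object$vi),
    rr = exp(object$yi),
    rr_low = exp(object$yi - .z95 * sqrt(object$vi)),
    rr_high = exp(object$yi + .z95 * sqrt(object$vi)),
    stringsAsFactors = FALSE)
  structure(list(fit = object, per_study = per_study), class = "summary.meta_dl")
}

#' @export
print.summary.meta_dl <- function(x, ...) {
  print(x$fit)
  cat("\nPer-study estimates:\n")
  print(x$per_study, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.meta_dl <- function(object, ...) c(pooled_log_effect = object$mu)

#' @export
confint.meta_dl <- function(object, parm, level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  out <- matrix(c(object$mu - z * object$se, object$mu + z * object$se), 1L)
  dimnames(out) <- list("pooled_log_effect",
                        sprintf("%g %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100))
  out
}

#' @export
residuals.meta_dl <- function(object, ...) {
  setNames(object$yi - object$mu, object$slab)
}

#' Funnel plot of a pooled analysis
#'
#' @param x a [meta_dl()] fit.
#' @param ... passed to [plot()].
#' @export
plot.meta_dl <- function(x, ...) {
  se <- sqrt(x$vi)
  plot(x$yi, se, ylim = rev(range(0, se)), pch = 19,
       xlab = "log effect", ylab = "standard error", ...)
  graphics::abline(v = x$mu, lty = 2)
  s <- seq(0, max(se), length.out = 50)
  graphics::lines(x$mu - .z95 * s, s, lty = 3)
  graphics::lines(x$mu + .z95 * s, s, lty = 3)
  invisible(x)
}

#' Subgroup pooling
#'
#' Pools each level of a label column separately and the whole table overall.
#'
#' @param records study table with a label column `label_key`.
#' @param label_key column name holding subgroup labels.
#' @param convert_or_to_rr passed to [to_log_effect()].
#' @return Named list of `meta_dl` fits, one per label, plus `"(overall)"`.
#' @export
subgroup_pool <- function(records, label_key, convert_or_to_rr = FALSE) {
  if (!label_key %in% names(records))
    stop("unknown label column: ", label_key)
  labels <- as.character(records[[label_key]])
  if (anyNA(labels)) stop("every record needs a ", label_key, " label")
  out <- lapply(split(seq_len(nrow(records)), labels), function(idx)
    meta_dl_records(records[idx, , drop = FALSE], convert_or_to_rr))
  out[["(overall)"]] <- meta_dl_records(records, convert_or_to_rr)
  out
}

#' Leave-one-study-out sensitivity analysis
#'
#' @param records study table with at least two studies.
#' @param convert_or_to_rr passed to [to_log_effect()].
#' @return Data frame with one row per omitted study plus a final `"(all)"`
#'   row: pooled RR, 95% CI, `tau2` and `i2_percent`.
#' @export
leave_one_study_out <- function(records, convert_or_to_rr = FALSE) {
  k <- nrow(records)
  if (k < 2L) stop("leave-one-study-out needs at least 2 studies")
  row_of <- function(fit, label)
    data.frame(omitted = label, k = fit$k, mu = fit$mu, se = fit$se,
               rr = fit$rr, rr_low = fit$rr_low, rr_high = fit$rr_high,
               tau2 = fit$tau2, i2_percent = fit$i2_percent,
               stringsAsFactors = FALSE)
  rows <- lapply(seq_len(k), function(i)
    row_of(meta_dl_records(records[-i, , drop = FALSE], convert_or_to_rr),
           as.character(records$study_id[i])))
  rows <- c(rows, list(row_of(meta_dl_records(records, convert_or_to_rr),
                              "(all)")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Egger regression test for small-study effects
#'
#' Ordinary regression of the standardized effects `y/se` on precision `1/se`;
#' the intercept measures funnel asymmetry and is tested with a t-test on
#' `k - 2` degrees of freedom.
#'
#' @param records study table with at least 3 studies.
#' @param convert_or_to_rr passed to [to_log_effect()].
#' @return List with `intercept`, `se`, `df`, `pvalue`.
#' @export
egger_bias_test <- function(records, convert_or_to_rr = FALSE) {
  yv <- .meta_yv(records, convert_or_to_rr)
  k <- nrow(yv)
  if (k < 3L) stop("Egger bias test needs at least 3 studies")
  se_i <- sqrt(yv$v)
  fit <- lm(I(yv$y / se_i) ~ I(1 / se_i))
  sm <- summary(fit)$coefficients
  list(intercept = unname(sm[1L, 1L]), se = unname(sm[1L, 2L]),
       df = k - 2L,
       pvalue = 2 * pt(-abs(sm[1L, 1L] / sm[1L, 2L]), df = k - 2L))
}

# Kendall's S and tie-corrected variance by brute-force pair counting
# (the conventional normal approximation z = S / sqrt(var)).
.kendall_stats <- function(u, v) {
  k <- length(u)
  S <- 0
  for (i in seq_len(k - 1L)) {
    du <- u[(i + 1L):k] - u[i]
    dv <- v[(i + 1L):k] - v[i]
    S <- S + sum(sign(du) * sign(dv))
  }
  tie_counts <- function(x) as.numeric(table(x))
  t_u <- tie_counts(u); t_v <- tie_counts(v)
  v0 <- k * (k - 1) * (2 * k + 5)
  vt <- sum(t_u * (t_u - 1) * (2 * t_u + 5))
  vv <- sum(t_v * (t_v - 1) * (2 * t_v + 5))
  v1 <- sum(t_u * (t_u - 1)) * sum(t_v * (t_v - 1)) / (2 * k * (k - 1))
  v2 <- if (k > 2)
    sum(t_u * (t_u - 1) * (t_u - 2)) * sum(t_v * (t_v - 1) * (t_v - 2)) /
      (9 * k * (k - 1) * (k - 2)) else 0
  n0 <- k * (k - 1) / 2
  n1 <- sum(t_u * (t_u - 1)) / 2
  n2 <- sum(t_v * (t_v - 1)) / 2
  list(S = S, var = (v0 - vt - vv) / 18 + v1 + v2,
       denom = sqrt((n0 - n1) * (n0 - n2)))
}

#' Begg rank-correlation test for publication bias
#'
#' Kendall rank correlation between the standardized deviates
#' `u_i = (y_i - mu_F) / sqrt(v_i - 1/sum(w))` and the variances `v_i`, with
#' the conventional tie-corrected normal approximation.  Studies whose
#' variance does not exceed the pooled variance within tolerance use a floored
#' denominator with a warning; with completely tied ranks the correlation is
#' reported as 0 with p = 1.
#'
#' @param records study table with at least 3 studies.
#' @param convert_or_to_rr passed to [to_log_effect()].
#' @return List with `tau` (Kendall tau-b) and `pvalue`.
#' @export
begg_bias_test <- function(records, convert_or_to_rr = FALSE) {
  yv <- .meta_yv(records, convert_or_to_rr)
  k <- nrow(yv)
  if (k < 3L) stop("Begg bias test needs at least 3 studies")
  w <- 1 / yv$v
  mu_f <- sum(w * yv$y) / sum(w)
  vstar <- yv$v - 1 / sum(w)
  if (any(vstar <= 1e-12)) {
    warning("pooled variance not smaller than some study variances; ",
            "flooring standardized-deviate denominators")
    vstar <- pmax(vstar, 1e-12)
  }
  u <- (yv$y - mu_f) / sqrt(vstar)
  ks <- .kendall_stats(u, yv$v)
  if (ks$denom <= 0 || ks$var <= 0)
    return(list(tau = 0, pvalue = 1))
  z <- ks$S / sqrt(ks$var)
  list(tau = ks$S / ks$denom, pvalue = 2 * pnorm(-abs(z)))
}

#' Funnel data table
#'
#' Deterministic (sorted by standard error) per-study table mirroring the
#' funnel plot, for machine output.
#'
#' @param records study table.
#' @param result the pooled [meta_dl()] fit used as the reference line.
#' @return Data frame with `study_id`, `y`, `se`, `pooled`.
#' @export
funnel_table <- function(records, result) {
  yv <- .meta_yv(records)
  out <- data.frame(study_id = yv$study_id, y = yv$y, se = sqrt(yv$v),
                    pooled = result$mu, stringsAsFactors = FALSE)
  out <- out[order(out$se, out$study_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a study table from tab-delimited text
#'
#' Expects a header with at least `study_id`, `estimate`, `ci_low`, `ci_high`;
#' `measure` defaults to RR when absent; extra columns (subgroup labels,
#' outcome, baseline_risk) are kept.
#'
#' @param path tab-delimited text file.
#' @return Validated study data frame.
#' @export
read_study_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "\"")
  need <- c("study_id", "estimate", "ci_low", "ci_high")
  absent <- setdiff(need, names(tab))
  if (length(absent))
    stop("study table lacks column(s): ", paste(absent, collapse = ", "))
  if (!"measure" %in% names(tab)) tab$measure <- "RR"
  .meta_yv(tab)  # validates positivity / interval ordering
  tab
}
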
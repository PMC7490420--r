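test_that("Wald ratio arithmetic, signs and the zero-gamma error", {
  expect_equal(mr_wald_ratio(0.10, 0.01, 0.02, 0.005),
               list(ratio = 0.2, se = 0.05))
  expect_equal(mr_wald_ratio(1, 0.1, 0, 0.3)$ratio, 0)
  expect_equal(mr_wald_ratio(-0.1, 0.01, 0.02, 0.005),
               list(ratio = -0.2, se = 0.05))
  expect_error(mr_wald_ratio(0, 0.01, 0.02, 0.005), "gamma = 0")
})

test_that("plain IVW closed form: exact fit, single-variant reduction, minimums", {
  h <- make_hset(c(1, 2), c(1, 2), c(1, 1))
  fit <- mr_ivw(h)
  expect_equal(fit$beta, 1)
  expect_equal(fit$se, sqrt(1 / 5))   # RSS = 0, floor keeps the unscaled se
  h1 <- make_hset(0.1, 0.02, 0.005, 0.01)
  fit1 <- mr_ivw(h1, scale_se = FALSE)
  wr <- mr_wald_ratio(0.1, 0.01, 0.02, 0.005)
  expect_equal(fit1$beta, wr$ratio)
  expect_equal(fit1$se, wr$se)
  expect_equal(fit1$or, exp(fit1$beta), tolerance = 1e-12)
  expect_error(mr_ivw(h1), "at least 2")
  expect_error(mr_ivw(make_hset(c(1, 2), c(1, 2), c(1, 1)), robust = TRUE),
               "at least 3")
})

test_that("plain IVW and Egger match lm() normal-equations oracles on random fixtures", {
  for (seed in 1:25) {
    h <- random_hset(n = 10, seed = 1000 + seed)
    for (sc in c(TRUE, FALSE)) {
      o <- ivw_oracle(h, scale_se = sc)
      fit <- mr_ivw(h, scale_se = sc)
      expect_equal(fit$beta, o$beta, tolerance = 1e-10)
      expect_equal(fit$se, o$se, tolerance = 1e-10)
      oe <- egger_oracle(h, scale_se = sc)
      eg <- mr_egger(h, scale_se = sc)
      expect_equal(eg$slope$beta, oe$beta, tolerance = 1e-10)
      expect_equal(eg$slope$se, oe$se_beta, tolerance = 1e-10)
      expect_equal(eg$intercept$estimate, oe$intercept, tolerance = 1e-10)
      expect_equal(eg$intercept$se, oe$se_intercept, tolerance = 1e-10)
    }
  }
})

test_that("Egger recovers exact-fit intercept and slope, and errors on degenerate input", {
  h <- make_hset(c(1, 2, 3), c(0.8, 1.3, 1.8), c(1, 1, 1))
  eg <- mr_egger(h)
  expect_equal(eg$intercept$estimate, 0.3, tolerance = 1e-12)
  expect_equal(eg$slope$beta, 0.5, tolerance = 1e-12)
  expect_equal(eg$intercept$or, exp(0.3), tolerance = 1e-12)
  # no pleiotropy: intercept estimate 0 to numerical precision
  h0 <- make_hset(c(1, 2, 3), 0.4 * c(1, 2, 3), c(1, 1, 1))
  expect_equal(mr_egger(h0)$intercept$estimate, 0, tolerance = 1e-10)
  expect_error(mr_egger(make_hset(c(1, 2), c(1, 2), c(1, 1))), "at least 3")
  expect_error(mr_egger(make_hset(c(1, 1, 1), c(1, 2, 3), c(1, 1, 1))),
               "unidentified")
})

test_that("weighted median interpolates the cumulative weights as defined", {
  # equal weights, symmetric ratios -> middle ratio
  h <- make_hset(c(1, 1, 1), c(1, 2, 3), c(1, 1, 1))
  expect_equal(mr_weighted_median(h, n_boot = 10, seed = 1)$beta, 2)
  # worked interpolation: weights (0.5, 0.25, 0.25) on ratios (1, 2, 3)
  # cumulative midpoints (0.25, 0.625, 0.875) -> 1 + 0.25/0.375
  h2 <- make_hset(c(sqrt(2), 1, 1), c(sqrt(2), 2, 3), c(1, 1, 1))
  expect_equal(mr_weighted_median(h2, n_boot = 10, seed = 1)$beta,
               1 + 0.25 / 0.375, tolerance = 1e-12)
  # equal weights at odd n equal the plain sample median of ratios
  set.seed(42)
  for (i in 1:5) {
    ratios <- rnorm(7)
    h3 <- make_hset(rep(1, 7), ratios, rep(1, 7))
    expect_equal(mr_weighted_median(h3, n_boot = 10, seed = 2)$beta,
                 median(ratios))
  }
  # identical seed, identical bootstrap se
  h4 <- random_hset(8, seed = 3)
  a <- mr_weighted_median(h4, n_boot = 200, seed = 11)
  b <- mr_weighted_median(h4, n_boot = 200, seed = 11)
  expect_identical(a$se, b$se)
  expect_error(mr_weighted_median(make_hset(c(1, 0, 2), c(1, 1, 1),
                                            c(1, 1, 1))), "gamma = 0")
})

test_that("Cochran's Q: exact fit, hand example, sign-flip invariance", {
  h <- make_hset(c(1, 2), c(0.5, 1), c(1, 1))
  q <- mr_cochran_q(h, beta = 0.5)
  expect_equal(q$Q, 0)
  expect_equal(q$pvalue, 1)
  q2 <- mr_cochran_q(make_hset(c(1, 1), c(0, 2), c(1, 1)), beta = 1)
  expect_equal(q2$Q, 2)
  expect_equal(q2$df, 1L)
  h3 <- random_hset(6, seed = 4)
  h3f <- make_hset(-h3$gamma, -h3$Gamma, h3$se_y, h3$se_x)
  expect_equal(mr_cochran_q(h3, 0.25)$Q, mr_cochran_q(h3f, 0.25)$Q)
})

test_that("leave-one-out produces n+1 rows and flags a planted dominant outlier", {
  h <- random_hset(4, seed = 6)
  loo <- mr_leave_one_out(h, method = "ivw")
  expect_equal(nrow(loo), 5L)
  expect_equal(loo$omitted, c(h$rsid, "(all)"))

  d <- gen_mr_dataset(n_snps = 12, outlier_indices = 3, outlier_offset = 10,
                      seed = 61)
  h2 <- harmonize(d$exposure, d$outcome)
  loo2 <- mr_leave_one_out(h2, method = "ivw")
  full_beta <- loo2$beta[loo2$omitted == "(all)"]
  shift <- abs(loo2$beta[loo2$omitted != "(all)"] - full_beta)
  expect_equal(loo2$omitted[which.max(shift)], d$truth$snps$rsid[3])
  expect_error(mr_leave_one_out(random_hset(3, seed = 1)), "at least 4")
})

test_that("homogeneous data give mutually overlapping leave-one-out intervals", {
  d <- gen_mr_dataset(n_snps = 15, seed = 62)
  h <- harmonize(d$exposure, d$outcome)
  loo <- mr_leave_one_out(h, method = "ivw")
  expect_true(max(loo$ci_low) < min(loo$ci_high))
})

test_that("mr_fit assembles all methods with coef/confint/residuals accessors", {
  d <- gen_mr_dataset(n_snps = 10, seed = 63)
  h <- harmonize(d$exposure, d$outcome)
  fit <- mr_fit(h, n_boot = 100, seed = 5)
  expect_s3_class(fit, "mr_fit")
  expect_named(fit$estimates, c("ivw_robust", "ivw", "egger_robust",
                                "egger", "weighted_median"))
  expect_named(fit$egger, c("egger_robust", "egger"))
  cf <- coef(fit)
  expect_equal(unname(cf["ivw"]), mr_ivw(h)$beta)
  ci <- confint(fit)
  expect_true(all(ci[, 1] < cf & cf < ci[, 2]))
  r <- residuals(fit, method = "ivw")
  expect_length(r, nrow(h))
  expect_equal(unname(r), (h$Gamma - mr_ivw(h)$beta * h$gamma) / h$se_y)
  tab <- summary(fit)$table
  expect_equal(nrow(tab), 5L)
  expect_true(all(tab$ci_low <= tab$beta & tab$beta <= tab$ci_high))
  expect_output(print(summary(fit)), "Cochran")
})

test_that("robust estimators track the plain ones on clean data and resist an outlier", {
  d <- gen_mr_dataset(n_snps = 20, seed = 64)
  h <- harmonize(d$exposure, d$outcome)
  expect_equal(mr_ivw(h, robust = TRUE)$beta, mr_ivw(h)$beta,
               tolerance = 0.05)
  d2 <- gen_mr_dataset(n_snps = 20, outlier_indices = 1, outlier_offset = 30,
                       seed = 64)
  h2 <- harmonize(d2$exposure, d2$outcome)
  err_rob <- abs(mr_ivw(h2, robust = TRUE)$beta - log(1.26))
  err_plain <- abs(mr_ivw(h2)$beta - log(1.26))
  expect_lt(err_rob, err_plain)
})
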
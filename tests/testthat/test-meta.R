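test_that("log-effect conversion follows the stated CI inversion and OR-to-RR formula", {
  yv <- to_log_effect(1.16, 1.09, 1.23)
  expect_equal(yv$y, log(1.16))
  expect_equal(sqrt(yv$v), (log(1.23) - log(1.09)) / (2 * 1.959964),
               tolerance = 1e-12)
  expect_equal(sqrt(yv$v), 0.030826, tolerance = 1e-4)
  # degenerate interval rejected
  expect_error(to_log_effect(1, 1, 1), "ci_low < estimate")
  expect_error(to_log_effect(-1, 0.5, 2), "positive")
  # OR -> RR with baseline risk
  conv <- to_log_effect(2, 1.5, 2.5, measure = "OR", baseline_risk = 0.1,
                        convert_or_to_rr = TRUE)
  expect_equal(exp(conv$y), 2 / (0.9 + 0.2), tolerance = 1e-12)
  # HR pooled as-is
  hr <- to_log_effect(1.3, 1.1, 1.6, measure = "HR")
  expect_equal(hr$y, log(1.3))
})

test_that("DL pooling reproduces the hand-worked example exactly", {
  fit <- meta_dl(y = c(0, 2), v = c(1, 1))
  expect_equal(fit$mu_fixed, 1)
  expect_equal(fit$Q, 2)
  expect_equal(fit$tau2, 1)
  expect_equal(fit$i2_percent, 50)
  expect_equal(fit$mu, 1)
  expect_equal(fit$se, 1)
})

test_that("DL degenerate cases: identical studies, single study, fixed-effect reduction", {
  fit <- meta_dl(rep(0.3, 4), rep(0.04, 4))
  expect_equal(fit$mu, 0.3)
  expect_equal(fit$Q, 0)
  expect_equal(fit$tau2, 0)
  expect_equal(fit$i2_percent, 0)
  one <- meta_dl(0.2, 0.01)
  expect_equal(one$mu, 0.2)
  expect_equal(one$se, 0.1)
  expect_true(is.na(one$Q))
  expect_equal(one$tau2, 0)
  expect_error(meta_dl(numeric(), numeric()), "at least one")
  # when Q <= df, tau2 = 0 and the pooled result is the fixed-effect one
  set.seed(2)
  y <- rnorm(6, 0.1, 0.01); v <- runif(6, 0.2, 0.4)
  fit2 <- meta_dl(y, v)
  if (fit2$tau2 == 0) expect_equal(fit2$mu, fit2$mu_fixed)
})

test_that("DL pooling matches independent oracles on random fixtures", {
  skip_if_not_installed("metafor")
  for (seed in 1:10) {
    set.seed(seed)
    k <- 20
    v <- runif(k, 0.01, 0.2)
    y <- rnorm(k, 0.15, sqrt(0.02 + v))
    fit <- meta_dl(y, v)
    o <- dl_oracle(y, v)
    expect_equal(fit$mu, o$mu, tolerance = 1e-12)
    expect_equal(fit$se, o$se, tolerance = 1e-12)
    expect_equal(fit$tau2, o$tau2, tolerance = 1e-12)
    rma <- metafor::rma(yi = y, vi = v, method = "DL")
    expect_equal(fit$mu, as.numeric(rma$beta), tolerance = 1e-10)
    expect_equal(fit$se, rma$se, tolerance = 1e-10)
    expect_equal(fit$tau2, rma$tau2, tolerance = 1e-10)
    expect_equal(fit$Q, rma$QE, tolerance = 1e-10)
    expect_equal(fit$i2_percent, rma$I2, tolerance = 1e-6)
  }
})

test_that("pooled estimate is equivariant to shifts and bounded by the inputs", {
  for (seed in 1:10) {
    set.seed(seed)
    k <- 8
    y <- rnorm(k, 0.2, 0.3); v <- runif(k, 0.01, 0.3)
    fit <- meta_dl(y, v)
    expect_gte(fit$mu, min(y)); expect_lte(fit$mu, max(y))
    sh <- meta_dl(y + 0.7, v)
    expect_equal(sh$mu, fit$mu + 0.7, tolerance = 1e-12)
    expect_equal(sh$Q, fit$Q, tolerance = 1e-10)
    expect_equal(sh$tau2, fit$tau2, tolerance = 1e-12)
    expect_equal(sh$i2_percent, fit$i2_percent, tolerance = 1e-10)
  }
})

test_that("subgroup pooling splits correctly and single-study groups return the study", {
  st <- random_studies(2, seed = 3)
  st$subgroup <- c("a", "b")
  out <- subgroup_pool(st, "subgroup")
  expect_named(out, c("a", "b", "(overall)"))
  yv <- to_log_effect(st$estimate, st$ci_low, st$ci_high)
  expect_equal(out$a$mu, yv$y[1])
  expect_equal(out$b$mu, yv$y[2])
  st$subgroup <- "a"
  out2 <- subgroup_pool(st, "subgroup")
  expect_equal(out2$a$mu, out2$`(overall)`$mu)
  expect_error(subgroup_pool(st, "nope"), "unknown label")
})

test_that("leave-one-study-out returns k+1 rows and reduces to the remaining study at k=2", {
  st <- random_studies(2, seed = 4)
  loo <- leave_one_study_out(st)
  expect_equal(nrow(loo), 3L)
  yv <- to_log_effect(st$estimate, st$ci_low, st$ci_high)
  expect_equal(loo$mu[1], yv$y[2])
  expect_equal(loo$mu[2], yv$y[1])
  st5 <- random_studies(5, seed = 5)
  expect_equal(nrow(leave_one_study_out(st5)), 6L)
  expect_error(leave_one_study_out(st5[1, ]), "at least 2")
  # homogeneous corpus: all reduced intervals overlap the full pool
  g <- gen_meta_studies(k_studies = 12, tau = 0.02, seed = 6)
  loo2 <- leave_one_study_out(g$studies)
  full <- loo2[loo2$omitted == "(all)", ]
  rest <- loo2[loo2$omitted != "(all)", ]
  expect_true(all(rest$rr_low < full$rr_high & rest$rr_high > full$rr_low))
})

test_that("Egger bias regression: symmetric input gives a zero intercept", {
  se <- c(0.1, 0.1, 0.2, 0.2, 0.3, 0.3)
  y <- 0.2 + c(-1, 1, -0.5, 0.5, -0.25, 0.25) * 0.1
  st <- data.frame(study_id = sprintf("s%d", 1:6), measure = "RR",
                   estimate = exp(y), ci_low = exp(y - 1.959964 * se),
                   ci_high = exp(y + 1.959964 * se))
  res <- egger_bias_test(st)
  # mirrored pairs at each se: deviations cancel in the normal equations
  expect_equal(res$intercept, 0, tolerance = 1e-10)
  expect_equal(res$df, 4L)
  expect_gt(res$pvalue, 0.5)
  expect_error(egger_bias_test(st[1:2, ]), "at least 3")
  expect_equal(egger_bias_test(st[1:3, ])$df, 1L)
})

test_that("Begg rank correlation matches brute-force pair counting and cor.test", {
  for (seed in 1:8) {
    st <- random_studies(9, seed = 200 + seed)
    res <- begg_bias_test(st)
    yv <- to_log_effect(st$estimate, st$ci_low, st$ci_high)
    w <- 1 / yv$v
    u <- (yv$y - sum(w * yv$y) / sum(w)) / sqrt(yv$v - 1 / sum(w))
    S <- kendall_brute(u, yv$v)
    expect_equal(res$tau, S / choose(9, 2), tolerance = 1e-12)
    ct <- suppressWarnings(cor.test(u, yv$v, method = "kendall"))
    expect_equal(res$tau, unname(ct$estimate), tolerance = 1e-10)
  }
  # perfect concordance
  st <- data.frame(study_id = c("a", "b", "c"), measure = "RR",
                   estimate = c(1.05, 1.3, 1.9), ci_low = c(0.95, 1.05, 1.2),
                   ci_high = c(1.16, 1.61, 3.01))
  res <- begg_bias_test(st)
  expect_equal(res$tau, 1)
})

test_that("funnel table is sorted by precision and round-trips through TSV", {
  st <- random_studies(7, seed = 12)
  fit <- meta_dl_records(st)
  ft <- funnel_table(st, fit)
  expect_equal(nrow(ft), 7L)
  expect_true(!is.unsorted(ft$se))
  expect_equal(unique(ft$pooled), fit$mu)
  tf <- tempfile(fileext = ".tsv")
  write.table(format(ft, digits = 17), tf, sep = "\t", quote = FALSE,
              row.names = FALSE)
  back <- read.table(tf, header = TRUE, sep = "\t")
  expect_equal(back$y, ft$y, tolerance = 1e-12)
  expect_equal(back$se, ft$se, tolerance = 1e-12)
})

test_that("study tables read from TSV are validated", {
  st <- random_studies(4, seed = 13)
  tf <- tempfile(fileext = ".tsv")
  write.table(st, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_study_table(tf)
  expect_equal(back$estimate, st$estimate)
  writeLines(c("study_id\testimate", "s1\t1.2"), tf)
  expect_error(read_study_table(tf), "lacks column")
})
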
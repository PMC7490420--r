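# Independent oracles and fixture builders shared across tests.

# Build a harmonized instrument set directly from effect vectors.
make_hset <- function(gamma, Gamma, se_y, se_x = rep(0.01, length(gamma)),
                      rsid = sprintf("rs%03d", seq_along(gamma))) {
  harmonized_instruments(rsid = rsid, gamma = gamma, se_x = se_x,
                         Gamma = Gamma, se_y = se_y)
}

# Random instrument fixture with a positive causal slope and mild noise.
random_hset <- function(n, seed) {
  set.seed(seed)
  gamma <- runif(n, 0.03, 0.2)
  se_x <- runif(n, 0.005, 0.02)
  se_y <- runif(n, 0.005, 0.03)
  Gamma <- 0.25 * gamma + rnorm(n, 0, se_y)
  make_hset(gamma, Gamma, se_y, se_x)
}

# Normal-equations oracle for plain IVW via lm(): weighted zero-intercept
# regression; unscaled se recovered by dividing out the lm dispersion.
ivw_oracle <- function(h, scale_se = TRUE) {
  w <- 1 / h$se_y^2
  fit <- lm(Gamma ~ 0 + gamma, data = h, weights = w)
  sm <- summary(fit)
  se_unscaled <- sm$coefficients[1, 2] / sm$sigma
  se <- if (scale_se) se_unscaled * max(1, sm$sigma) else se_unscaled
  list(beta = unname(coef(fit)[1]), se = se)
}

# Normal-equations oracle for plain MR-Egger via lm() with intercept.
egger_oracle <- function(h, scale_se = TRUE) {
  w <- 1 / h$se_y^2
  fit <- lm(Gamma ~ gamma, data = h, weights = w)
  sm <- summary(fit)
  se_unscaled <- sm$coefficients[, 2] / sm$sigma
  se <- if (scale_se) se_unscaled * max(1, sm$sigma) else se_unscaled
  list(intercept = unname(coef(fit)[1]), beta = unname(coef(fit)[2]),
       se_intercept = unname(se[1]), se_beta = unname(se[2]))
}

# Two-pass DL oracle written independently of the implementation.
dl_oracle <- function(y, v) {
  w <- 1 / v
  mu_f <- sum(w * y) / sum(w)
  Q <- sum(w * (y - mu_f)^2)
  tau2 <- max(0, (Q - (length(y) - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (v + tau2)
  list(mu = sum(ws * y) / sum(ws), se = sqrt(1 / sum(ws)), Q = Q, tau2 = tau2)
}

# Brute-force Kendall concordant/discordant pair counting.
kendall_brute <- function(u, v) {
  k <- length(u)
  S <- 0
  for (i in 1:(k - 1)) for (j in (i + 1):k)
    S <- S + sign(u[j] - u[i]) * sign(v[j] - v[i])
  S
}

# Random study table on the RR scale.
random_studies <- function(k, seed, mu = log(1.2), tau = 0.1) {
  set.seed(seed)
  se <- runif(k, 0.05, 0.4)
  y <- rnorm(k, rnorm(k, mu, tau), se)
  data.frame(study_id = sprintf("s%02d", 1:k), measure = "RR",
             estimate = exp(y), ci_low = exp(y - 1.959964 * se),
             ci_high = exp(y + 1.959964 * se),
             subgroup = rep(c("a", "b"), length.out = k),
             stringsAsFactors = FALSE)
}

# Canonical identity column map for files written by write_summary_stats().
identity_map <- function() {
  cols <- c("rsid", "chrom", "pos", "effect_allele", "other_allele", "eaf",
            "beta", "se", "pvalue", "n")
  setNames(cols, cols)
}
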
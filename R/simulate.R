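# Seeded generators for every input the pipeline consumes, with ground truth
# attached.  One user-facing seed per dataset; independent sub-streams per
# component so, e.g., adding background variants does not shift the
# instrument draws.

# GWAS standard error of a per-allele effect.  Quantitative traits assume a
# standardized phenotype: se = 1/sqrt(2*maf*(1-maf)*n).  Binary traits use the
# log-OR variance approximation 1/sqrt(2*maf*(1-maf)*n*phi*(1-phi)) with phi
# the case fraction.
.gwas_se <- function(maf, n, case_fraction = NULL) {
  denom <- 2 * maf * (1 - maf) * n
  if (!is.null(case_fraction)) denom <- denom * case_fraction * (1 - case_fraction)
  1 / sqrt(denom)
}

# Two-sided normal p floored away from zero so records always satisfy the
# pvalue > 0 invariant even for very strong signals.
.p_from_z <- function(z) pmax(2 * pnorm(-abs(z)), 1e-300)

.nonpal_pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                       c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
.pal_pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Generate a synthetic two-sample MR dataset with ground truth
#'
#' Emits the three GWAS summary-statistic sets the genetic arm consumes
#' (exposure, outcome, disease used for exclusion), a block-structured LD
#' matrix, and a ground-truth record.  Defaults emulate the study conditions
#' of a fasting-glucose -> coronary-artery-disease analysis: 28 instruments,
#' causal log-odds `log(1.26)` per mmol/L, exposure GWAS n = 133,010
#' (quantitative), outcome GWAS n = 296,525 with case fraction 0.1165
#' (binary), disease arm n = 898,130 with case fraction 0.0825.
#'
#' Per variant: `maf ~ U(maf_range)`; true exposure effect magnitude
#' `~ U(gamma_range)` with random sign; observed effects are the truth plus
#' normal noise at the GWAS standard errors; the variant-outcome mean is
#' `beta_true * gamma + alpha` where the pleiotropic effect `alpha` follows
#' `pleiotropy_mode` (`"none"`, `"balanced"` `N(0, sd^2)`, `"directional"`
#' `N(sd, (sd/2)^2)`, or `"inside_violating"` correlated with `gamma`),
#' applied to a `pleiotropy_frac` fraction of instruments.  Outliers add
#' `outlier_offset * se_y` to the observed outcome effect.  Optional
#' corruption (strand flips, allele swaps, palindromic allele pairs) is
#' applied to the outcome records only and recorded in the truth so
#' harmonization can be validated against it.
#'
#' @param n_snps number of instrument variants.
#' @param beta_true causal effect of the exposure on the outcome (log-odds per
#'   exposure unit).
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param case_fraction_outcome case fraction of the (binary) outcome GWAS.
#' @param maf_range,gamma_range uniform ranges for minor-allele frequency and
#'   true exposure-effect magnitude.
#' @param pleiotropy_mode,pleiotropy_sd,pleiotropy_frac pleiotropy regime,
#'   scale, and affected fraction of instruments.
#' @param outlier_indices,outlier_offset instrument indices receiving an
#'   additive outcome offset of `outlier_offset * se_y`.
#' @param n_null_snps background variants with no effect on anything.
#' @param disease_assoc_indices instrument indices planted with a disease
#'   p-value below 0.05 (all other variants draw null disease p-values).
#' @param n_disease,case_fraction_disease disease-arm GWAS size and case
#'   fraction.
#' @param frac_strand_flip,frac_allele_swap,frac_palindromic corruption
#'   fractions (strand flips and allele swaps may overlap; palindromic
#'   fraction decides which variants get A/T or C/G alleles).
#' @param ld_block_size,ld_r2_within LD structure: instruments come in blocks
#'   of `ld_block_size` adjacent variants sharing r-squared `ld_r2_within`.
#' @param seed integer seed; same seed, same dataset.
#' @return List with `exposure`, `outcome`, `disease` ([summary_stats()]),
#'   `ld` ([ld_matrix()]) and `truth` (config echo plus a per-variant data
#'   frame holding true effects, pleiotropy, outlier/corruption flags, and the
#'   pre-corruption observed effect pairs in exposure-positive orientation).
#' @export
gen_mr_dataset <- function(n_snps = 28, beta_true = log(1.26),
                           n_exposure = 133010, n_outcome = 296525,
                           case_fraction_outcome = 0.1165,
                           maf_range = c(0.1, 0.5),
                           gamma_range = c(0.05, 0.15),
                           pleiotropy_mode = c("none", "balanced",
                                               "directional", "inside_violating"),
                           pleiotropy_sd = 0.01, pleiotropy_frac = 1,
                           outlier_indices = integer(), outlier_offset = 0,
                           n_null_snps = 0, disease_assoc_indices = integer(),
                           n_disease = 898130, case_fraction_disease = 0.0825,
                           frac_strand_flip = 0, frac_allele_swap = 0,
                           frac_palindromic = 0,
                           ld_block_size = 1, ld_r2_within = 0, seed) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (missing(seed)) stop("gen_mr_dataset requires a seed")
  if (n_snps < 1) stop("n_snps must be at least 1")
  stopifnot(maf_range[1] > 0, maf_range[2] < 1, maf_range[1] <= maf_range[2],
            gamma_range[1] <= gamma_range[2],
            all(c(frac_strand_flip, frac_allele_swap, frac_palindromic) >= 0),
            all(c(frac_strand_flip, frac_allele_swap, frac_palindromic) <= 1),
            pleiotropy_frac >= 0, pleiotropy_frac <= 1,
            all(outlier_indices %in% seq_len(n_snps)),
            all(disease_assoc_indices %in% seq_len(n_snps)),
            ld_block_size >= 1, ld_r2_within >= 0, ld_r2_within <= 1)

  rsid <- sprintf("rs%07d", seq_len(n_snps))

  # --- variant-level parameters -------------------------------------------
  set.seed(.sub_seed(seed, 1L))
  maf <- runif(n_snps, maf_range[1], maf_range[2])
  gamma_true <- runif(n_snps, gamma_range[1], gamma_range[2]) *
    sample(c(-1, 1), n_snps, replace = TRUE)
  n_pal <- round(frac_palindromic * n_snps)
  pal_idx <- if (n_pal > 0) sample.int(n_snps, n_pal) else integer()
  is_pal <- seq_len(n_snps) %in% pal_idx
  alleles <- .nonpal_pairs[sample.int(nrow(.nonpal_pairs), n_snps,
                                      replace = TRUE), , drop = FALSE]
  if (n_pal > 0)
    alleles[pal_idx, ] <- .pal_pairs[sample.int(nrow(.pal_pairs), n_pal,
                                                replace = TRUE), , drop = FALSE]

  se_x <- .gwas_se(maf, n_exposure)
  se_y <- .gwas_se(maf, n_outcome, case_fraction_outcome)
  se_d <- .gwas_se(maf, n_disease, case_fraction_disease)

  # --- observed exposure effects ------------------------------------------
  set.seed(.sub_seed(seed, 2L))
  gamma_obs <- rnorm(n_snps, gamma_true, se_x)

  # --- pleiotropy ----------------------------------------------------------
  set.seed(.sub_seed(seed, 3L))
  n_inv <- round(pleiotropy_frac * n_snps)
  invalid <- if (pleiotropy_mode == "none" || n_inv == 0) integer()
             else sample.int(n_snps, n_inv)
  alpha <- numeric(n_snps)
  if (length(invalid)) {
    alpha[invalid] <- switch(pleiotropy_mode,
      balanced = rnorm(length(invalid), 0, pleiotropy_sd),
      directional = rnorm(length(invalid), pleiotropy_sd, pleiotropy_sd / 2),
      inside_violating = 0.5 * pleiotropy_sd * gamma_true[invalid] /
        mean(abs(gamma_true)) +
        rnorm(length(invalid), 0, pleiotropy_sd / 2),
      none = 0)
  }

  # --- observed outcome effects -------------------------------------------
  set.seed(.sub_seed(seed, 4L))
  Gamma_obs <- rnorm(n_snps, beta_true * gamma_true + alpha, se_y)
  is_outlier <- seq_len(n_snps) %in% outlier_indices
  Gamma_obs[is_outlier] <- Gamma_obs[is_outlier] +
    outlier_offset * se_y[is_outlier]

  # --- corruption of the outcome records ----------------------------------
  set.seed(.sub_seed(seed, 5L))
  n_flip <- round(frac_strand_flip * n_snps)
  n_swap <- round(frac_allele_swap * n_snps)
  flip_idx <- if (n_flip > 0) sample.int(n_snps, n_flip) else integer()
  swap_idx <- if (n_swap > 0) sample.int(n_snps, n_swap) else integer()
  strand_flipped <- seq_len(n_snps) %in% flip_idx
  allele_swapped <- seq_len(n_snps) %in% swap_idx

  out_ea <- alleles[, 1L]; out_oa <- alleles[, 2L]
  out_beta <- Gamma_obs
  out_eaf <- maf
  # allele swap: labels exchanged, effect negated, frequency reflected
  out_beta[allele_swapped] <- -out_beta[allele_swapped]
  out_eaf[allele_swapped] <- 1 - out_eaf[allele_swapped]
  tmp <- out_ea[allele_swapped]
  out_ea[allele_swapped] <- out_oa[allele_swapped]
  out_oa[allele_swapped] <- tmp
  # strand flip: pure relabelling to the complementary strand
  comp_ea <- .complement(out_ea); comp_oa <- .complement(out_oa)
  out_ea[strand_flipped] <- comp_ea[strand_flipped]
  out_oa[strand_flipped] <- comp_oa[strand_flipped]

  # --- disease arm ---------------------------------------------------------
  set.seed(.sub_seed(seed, 6L))
  disease_assoc <- seq_len(n_snps) %in% disease_assoc_indices
  p_d <- runif(n_snps)
  p_d[disease_assoc] <- runif(sum(disease_assoc), 1e-4, 0.049)
  z_d <- qnorm(p_d / 2, lower.tail = FALSE) *
    sample(c(-1, 1), n_snps, replace = TRUE)
  beta_d <- z_d * se_d

  # --- background null variants -------------------------------------------
  set.seed(.sub_seed(seed, 7L))
  if (n_null_snps > 0) {
    null_rsid <- sprintf("rs9%06d", seq_len(n_null_snps))
    null_maf <- runif(n_null_snps, maf_range[1], maf_range[2])
    null_alleles <- .nonpal_pairs[sample.int(nrow(.nonpal_pairs), n_null_snps,
                                             replace = TRUE), , drop = FALSE]
    null_se_x <- .gwas_se(null_maf, n_exposure)
    null_se_y <- .gwas_se(null_maf, n_outcome, case_fraction_outcome)
    null_se_d <- .gwas_se(null_maf, n_disease, case_fraction_disease)
    null_gx <- rnorm(n_null_snps, 0, null_se_x)
    null_gy <- rnorm(n_null_snps, 0, null_se_y)
    null_gd <- rnorm(n_null_snps, 0, null_se_d)
  }

  # --- positions: blocks of adjacent variants, blocks far apart ------------
  block <- (seq_len(n_snps) - 1L) %/% ld_block_size
  chrom <- as.character(block %% 22L + 1L)
  pos <- 1e6 + (block %/% 22L) * 5e6 +
    ((seq_len(n_snps) - 1L) %% ld_block_size) * 1e4

  mk_set <- function(rs, chr, p, ea, oa, eaf, beta, se, n, trait_id,
                     trait_type, unit) {
    summary_stats(data.frame(
      rsid = rs, chrom = chr, pos = p, effect_allele = ea, other_allele = oa,
      eaf = eaf, beta = beta, se = se,
      pvalue = .p_from_z(beta / se), n = n, stringsAsFactors = FALSE),
      trait_id = trait_id, trait_type = trait_type, unit = unit)
  }

  exp_df <- list(rs = rsid, chr = chrom, p = pos, ea = alleles[, 1L],
                 oa = alleles[, 2L], eaf = maf, beta = gamma_obs, se = se_x)
  out_df <- list(rs = rsid, chr = chrom, p = pos, ea = out_ea, oa = out_oa,
                 eaf = out_eaf, beta = out_beta, se = se_y)
  dis_df <- list(rs = rsid, chr = chrom, p = pos, ea = alleles[, 1L],
                 oa = alleles[, 2L], eaf = maf, beta = beta_d, se = se_d)
  if (n_null_snps > 0) {
    null_chrom <- as.character((seq_len(n_null_snps) - 1L) %% 22L + 1L)
    null_pos <- 2e8 + ((seq_len(n_null_snps) - 1L) %/% 22L) * 5e6
    add <- function(base, beta, se) {
      list(rs = c(base$rs, null_rsid), chr = c(base$chr, null_chrom),
           p = c(base$p, null_pos),
           ea = c(base$ea, null_alleles[, 1L]),
           oa = c(base$oa, null_alleles[, 2L]),
           eaf = c(base$eaf, null_maf),
           beta = c(base$beta, beta), se = c(base$se, se))
    }
    exp_df <- add(exp_df, null_gx, null_se_x)
    out_df <- add(out_df, null_gy, null_se_y)
    dis_df <- add(dis_df, null_gd, null_se_d)
  }

  exposure <- mk_set(exp_df$rs, exp_df$chr, exp_df$p, exp_df$ea, exp_df$oa,
                     exp_df$eaf, exp_df$beta, exp_df$se, n_exposure,
                     "fasting_glucose_synth", "quantitative", "mmol/L")
  outcome <- mk_set(out_df$rs, out_df$chr, out_df$p, out_df$ea, out_df$oa,
                    out_df$eaf, out_df$beta, out_df$se, n_outcome,
                    "outcome_synth", "binary", "log-odds")
  disease <- mk_set(dis_df$rs, dis_df$chr, dis_df$p, dis_df$ea, dis_df$oa,
                    dis_df$eaf, dis_df$beta, dis_df$se, n_disease,
                    "t2d_synth", "binary", "log-odds")

  # --- LD matrix: block-diagonal over instruments, nulls independent -------
  all_ids <- exp_df$rs
  r2 <- diag(1, length(all_ids))
  dimnames(r2) <- list(all_ids, all_ids)
  if (ld_block_size > 1 && ld_r2_within > 0) {
    for (b in unique(block)) {
      idx <- which(block == b)
      if (length(idx) > 1) {
        r2[idx, idx] <- ld_r2_within
        r2[cbind(idx, idx)] <- 1
      }
    }
  }
  ld <- ld_matrix(r2)

  orient <- ifelse(gamma_obs < 0, -1, 1)
  truth_snps <- data.frame(
    rsid = rsid, maf = maf, gamma_true = gamma_true, alpha = alpha,
    is_outlier = is_outlier, disease_assoc = disease_assoc,
    palindromic = is_pal, strand_flipped = strand_flipped,
    allele_swapped = allele_swapped,
    gamma_obs = gamma_obs, Gamma_obs = Gamma_obs,
    se_x = se_x, se_y = se_y,
    gamma_obs_oriented = orient * gamma_obs,
    Gamma_obs_oriented = orient * Gamma_obs,
    stringsAsFactors = FALSE)

  list(exposure = exposure, outcome = outcome, disease = disease, ld = ld,
       truth = list(beta_true = beta_true, seed = seed,
                    pleiotropy_mode = pleiotropy_mode,
                    pleiotropy_sd = pleiotropy_sd,
                    invalid_indices = sort(invalid),
                    outlier_indices = sort(outlier_indices),
                    n_snps = n_snps, n_null_snps = n_null_snps,
                    snps = truth_snps))
}

#' Generate a synthetic observational study corpus with ground truth
#'
#' Study-level true log effects are `N(mu_true, tau^2)`; standard errors are
#' uniform on `se_range`; observed log effects add normal noise plus an
#' optional small-study term `small_study_bias * se` (a planted
#' publication-bias signal).  Estimates are emitted as RR with 95% intervals
#' `exp(y +/- 1.959964 * se)`.  Defaults emulate a coronary-artery-disease
#' corpus: 21 studies pooled around RR 1.16 with modest between-study spread.
#'
#' @param k_studies number of studies.
#' @param mu_true pooled log relative risk.
#' @param tau between-study standard deviation.
#' @param se_range uniform range of within-study standard errors.
#' @param labels subgroup labels assigned round-robin.
#' @param small_study_bias coefficient linking bias to the standard error.
#' @param outcome outcome label attached to every study.
#' @param seed integer seed.
#' @return List with `studies` (a study table usable by [meta_dl_records()])
#'   and `truth` (config echo plus per-study true effects).
#' @export
gen_meta_studies <- function(k_studies = 21, mu_true = log(1.16), tau = 0.05,
                             se_range = c(0.05, 0.30),
                             labels = c("IFG-ADA", "IFG-WHO", "IGT", "HbA1c"),
                             small_study_bias = 0, outcome = "CAD", seed) {
  if (missing(seed)) stop("gen_meta_studies requires a seed")
  stopifnot(k_studies >= 1, tau >= 0, se_range[1] > 0,
            se_range[1] <= se_range[2])
  set.seed(.sub_seed(seed, 11L))
  theta <- rnorm(k_studies, mu_true, tau)
  se <- runif(k_studies, se_range[1], se_range[2])
  y <- rnorm(k_studies, theta + small_study_bias * se, se)
  studies <- data.frame(
    study_id = sprintf("study_%02d", seq_len(k_studies)),
    measure = "RR",
    estimate = exp(y),
    ci_low = exp(y - .z95 * se),
    ci_high = exp(y + .z95 * se),
    subgroup = rep(labels, length.out = k_studies),
    outcome = outcome,
    stringsAsFactors = FALSE)
  list(studies = studies,
       truth = list(mu_true = mu_true, tau = tau, seed = seed,
                    small_study_bias = small_study_bias,
                    theta = theta, y = y, se = se))
}
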
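# Instrument construction: significance filtering, disease-association
# exclusion, greedy LD clumping, and exposure-outcome harmonization.

#' Select genome-wide significant variants
#'
#' Keeps variants with `pvalue < p_threshold` (strict inequality; a variant at
#' exactly the threshold is excluded).
#'
#' @param exposure a [summary_stats()] set.
#' @param p_threshold significance threshold, default the conventional
#'   genome-wide `5e-8`.
#' @return The significant subset (possibly empty).
#' @export
select_significant <- function(exposure, p_threshold = 5e-8) {
  stopifnot(inherits(exposure, "summary_stats"))
  .subset_ss(exposure, exposure$pvalue < p_threshold)
}

#' Exclude candidates associated with a disease
#'
#' Retains candidate variants whose p-value in the disease GWAS is strictly
#' greater than `p_exclusion` (their glycaemic signal carries no nominal
#' disease signal).  Candidates absent from the disease set cannot be
#' certified non-associated and are dropped, counted separately.
#'
#' @param candidates,disease [summary_stats()] sets.
#' @param p_exclusion exclusion threshold, default 0.05.
#' @return Retained subset with an `"exclusion_report"` attribute
#'   (`n_candidates`, `n_excluded_associated`, `n_dropped_missing`,
#'   `excluded_rsids`, `missing_rsids`).
#' @export
exclude_disease_associated <- function(candidates, disease, p_exclusion = 0.05) {
  stopifnot(inherits(candidates, "summary_stats"),
            inherits(disease, "summary_stats"))
  m <- match(candidates$rsid, disease$rsid)
  missing <- is.na(m)
  assoc <- !missing & disease$pvalue[m] <= p_exclusion
  keep <- !missing & !assoc
  out <- .subset_ss(candidates, keep)
  attr(out, "exclusion_report") <- list(
    n_candidates = nrow(candidates),
    n_excluded_associated = sum(assoc),
    n_dropped_missing = sum(missing),
    excluded_rsids = candidates$rsid[assoc],
    missing_rsids = candidates$rsid[missing])
  out
}

#' Greedy LD clumping
#'
#' Candidates are sorted by ascending p-value (ties broken by rsid); the best
#' remaining variant is accepted and every remaining variant on the same
#' chromosome within `window_kb` kilobases with squared correlation
#' `>= r2_threshold` against it is removed.  Cross-chromosome pairs never
#' clump; variants absent from `ld` (or lacking a position) are treated as
#' independent.  Every retained pair within the window therefore has
#' `r2 < r2_threshold`.
#'
#' @param candidates a [summary_stats()] set with `chrom`/`pos` filled in.
#' @param ld an [ld_matrix()].
#' @param r2_threshold clumping threshold on r-squared, default 0.2.
#' @param window_kb window half-width in kilobases, default 1000.
#' @return Retained subset with a `"clump_report"` attribute data frame
#'   (`rsid`, `kept`, `removed_by`).
#' @export
ld_clump <- function(candidates, ld, r2_threshold = 0.2, window_kb = 1000) {
  stopifnot(inherits(candidates, "summary_stats"))
  df <- as.data.frame(candidates)
  ord <- order(df$pvalue, df$rsid)
  df <- df[ord, , drop = FALSE]
  n <- nrow(df)
  in_ld <- df$rsid %in% rownames(ld)
  status <- rep(NA_character_, n)     # NA = undecided, "" = kept, else remover
  for (i in seq_len(n)) {
    if (!is.na(status[i])) next
    status[i] <- ""
    later <- which(is.na(status))
    if (!length(later)) next
    same_chr <- !is.na(df$chrom[later]) & !is.na(df$chrom[i]) &
      df$chrom[later] == df$chrom[i]
    in_window <- same_chr & !is.na(df$pos[later]) & !is.na(df$pos[i]) &
      abs(df$pos[later] - df$pos[i]) <= window_kb * 1000
    r2 <- rep(0, length(later))
    lookup <- in_window & in_ld[later] & in_ld[i]
    if (any(lookup))
      r2[lookup] <- ld[cbind(df$rsid[later[lookup]],
                             rep(df$rsid[i], sum(lookup)))]
    clumped <- in_window & r2 >= r2_threshold
    status[later[clumped]] <- df$rsid[i]
  }
  kept <- status == ""
  out <- .subset_ss(candidates, candidates$rsid %in% df$rsid[kept])
  attr(out, "clump_report") <- data.frame(
    rsid = df$rsid, kept = kept,
    removed_by = ifelse(kept, NA_character_, status),
    stringsAsFactors = FALSE)
  out
}

#' Construct a harmonized instrument set directly
#'
#' Low-level constructor for the aligned per-variant exposure/outcome effect
#' pairs consumed by the estimators: `gamma`/`se_x` are the variant-exposure
#' effect and its standard error, `Gamma`/`se_y` the variant-outcome ones.
#' [harmonize()] builds this from two summary-statistic sets; simulation
#' studies may build it directly.
#'
#' @param rsid variant identifiers (unique).
#' @param gamma,se_x,Gamma,se_y numeric vectors; both standard errors must be
#'   positive.
#' @param eaf_x,eaf_y optional effect-allele frequencies.
#' @param exposure_id,outcome_id trait labels.
#' @return A `harmonized_instruments` data frame.
#' @export
harmonized_instruments <- function(rsid, gamma, se_x, Gamma, se_y,
                                   eaf_x = NA_real_, eaf_y = NA_real_,
                                   exposure_id = "exposure",
                                   outcome_id = "outcome") {
  df <- data.frame(rsid = as.character(rsid), gamma = gamma, se_x = se_x,
                   Gamma = Gamma, se_y = se_y, eaf_x = eaf_x, eaf_y = eaf_y,
                   stringsAsFactors = FALSE)
  if (nrow(df) < 1L) stop("harmonized set needs at least one variant")
  if (anyDuplicated(df$rsid)) stop("duplicate rsid(s)")
  if (any(!is.finite(df$se_x)) || any(df$se_x <= 0) ||
      any(!is.finite(df$se_y)) || any(df$se_y <= 0))
    stop("all standard errors must be positive")
  structure(df, class = c("harmonized_instruments", "data.frame"),
            exposure_id = exposure_id, outcome_id = outcome_id)
}

#' @export
print.harmonized_instruments <- function(x, ...) {
  cat(sprintf("Harmonized instruments: %s -> %s, %d variant(s)\n",
              attr(x, "exposure_id"), attr(x, "outcome_id"), nrow(x)))
  print(head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... and %d more rows\n", nrow(x) - 6L))
  log <- attr(x, "harmonization_log")
  if (!is.null(log)) {
    cat("Harmonization actions:\n")
    print(table(log$action))
  }
  invisible(x)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome association of every instrument variant to the exposure
#' effect allele.  For each shared rsid: identical alleles are kept; swapped
#' alleles flip the sign of the outcome effect (and reflect its allele
#' frequency); strand-complement and swapped-complement configurations are
#' complemented first and then treated the same way.  Palindromic variants
#' (A/T, C/G) cannot be resolved from alleles: under `palindrome_policy =
#' "drop"` they are removed; under `"infer"` the two allele frequencies decide
#' (same side of 0.5 keeps the outcome effect, opposite sides flip it) unless
#' either frequency is missing or falls inside the ambiguity window
#' `[eaf_ambiguity, 1 - eaf_ambiguity]`, in which case the variant is removed.
#' Variants missing from the outcome set or with irreconcilable alleles are
#' removed.  Finally every exposure effect is re-oriented positive, flipping
#' the exposure and outcome signs together (required for Egger-regression
#' identifiability; a no-op for IVW and the weighted median).
#'
#' @param exposure instrument variants ([summary_stats()]).
#' @param outcome outcome GWAS ([summary_stats()]).
#' @param palindrome_policy `"infer"` (default) or `"drop"`.
#' @param eaf_ambiguity lower edge of the frequency window in which palindromic
#'   alignment is considered ambiguous; default 0.42.
#' @return A [harmonized_instruments()] data frame with a
#'   `"harmonization_log"` attribute recording, for every candidate variant,
#'   the action taken (`kept`, `sign_flipped`, `palindrome_aligned`,
#'   `dropped_palindrome`, `dropped_mismatch`, `dropped_missing`).
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("infer", "drop"),
                      eaf_ambiguity = 0.42) {
  palindrome_policy <- match.arg(palindrome_policy)
  stopifnot(inherits(exposure, "summary_stats"),
            inherits(outcome, "summary_stats"))
  ex <- as.data.frame(exposure)
  ou <- as.data.frame(outcome)
  n <- nrow(ex)
  m <- match(ex$rsid, ou$rsid)
  action <- rep(NA_character_, n)
  action[is.na(m)] <- "dropped_missing"

  Gamma <- se_y <- eaf_y <- rep(NA_real_, n)
  hit <- !is.na(m)
  Gamma[hit] <- ou$beta[m[hit]]
  se_y[hit] <- ou$se[m[hit]]
  eaf_y[hit] <- ou$eaf[m[hit]]
  ea_y <- oa_y <- rep(NA_character_, n)
  ea_y[hit] <- ou$effect_allele[m[hit]]
  oa_y[hit] <- ou$other_allele[m[hit]]

  pal <- classify_palindromic(ex$effect_allele, ex$other_allele)
  cy <- .complement(ea_y)
  cz <- .complement(oa_y)
  same <- hit & ea_y == ex$effect_allele & oa_y == ex$other_allele
  swap <- hit & ea_y == ex$other_allele & oa_y == ex$effect_allele
  comp_same <- hit & !is.na(cy) & !is.na(cz) &
    cy == ex$effect_allele & cz == ex$other_allele
  comp_swap <- hit & !is.na(cy) & !is.na(cz) &
    cy == ex$other_allele & cz == ex$effect_allele
  reconcilable <- same | swap | comp_same | comp_swap
  action[hit & !reconcilable] <- "dropped_mismatch"

  # Palindromic variants: allele configuration is uninformative (a strand flip
  # looks like an allele swap); orientation is decided by frequency alone.
  pal_hit <- hit & reconcilable & pal
  if (palindrome_policy == "drop") {
    action[pal_hit] <- "dropped_palindrome"
  } else {
    ambiguous <- function(f) is.na(f) | (f >= eaf_ambiguity & f <= 1 - eaf_ambiguity)
    amb <- ambiguous(ex$eaf) | ambiguous(eaf_y)
    action[pal_hit & amb] <- "dropped_palindrome"
    ok <- pal_hit & !amb
    flip <- ok & (ex$eaf > 0.5) != (eaf_y > 0.5)
    Gamma[flip] <- -Gamma[flip]
    eaf_y[flip] <- 1 - eaf_y[flip]
    action[ok] <- "palindrome_aligned"
  }

  # Non-palindromic variants
  np <- hit & reconcilable & !pal
  action[np & (same | comp_same)] <- "kept"
  do_flip <- np & (swap | comp_swap)
  Gamma[do_flip] <- -Gamma[do_flip]
  eaf_y[do_flip] <- 1 - eaf_y[do_flip]
  action[do_flip] <- "sign_flipped"

  keep <- action %in% c("kept", "sign_flipped", "palindrome_aligned")
  if (!any(keep))
    stop("harmonization removed every candidate variant (step: harmonize)")

  gamma <- ex$beta[keep]
  eaf_x <- ex$eaf[keep]
  ea <- ex$effect_allele[keep]
  oa <- ex$other_allele[keep]
  G <- Gamma[keep]; fy <- eaf_y[keep]
  # orient exposure effects positive, flipping both effects together
  neg <- gamma < 0
  gamma[neg] <- -gamma[neg]
  G[neg] <- -G[neg]
  eaf_x[neg] <- 1 - eaf_x[neg]
  fy[neg] <- 1 - fy[neg]
  tmp <- ea[neg]; ea[neg] <- oa[neg]; oa[neg] <- tmp

  out <- harmonized_instruments(
    rsid = ex$rsid[keep], gamma = gamma, se_x = ex$se[keep],
    Gamma = G, se_y = se_y[keep], eaf_x = eaf_x, eaf_y = fy,
    exposure_id = attr(exposure, "trait_id"),
    outcome_id = attr(outcome, "trait_id"))
  out$effect_allele <- ea
  out$other_allele <- oa
  out$chrom <- ex$chrom[keep]
  out$pos <- ex$pos[keep]
  attr(out, "harmonization_log") <- data.frame(
    rsid = ex$rsid, action = action, stringsAsFactors = FALSE)
  out
}
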
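# Orchestration of the two analysis arms from a single config list, and
# deterministic machine-readable report rendering.

.load_ss <- function(x, map, trait_id, trait_type, unit = NA_character_) {
  if (inherits(x, "summary_stats")) return(x)
  read_summary_stats(x, column_map = map, trait_id = trait_id,
                     trait_type = trait_type, unit = unit)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the genetic (Mendelian-randomization) arm
#'
#' Executes the full instrument-construction and estimation pipeline:
#' significance selection, disease-association exclusion, LD clumping,
#' harmonization, the estimator battery of [mr_fit()], Cochran's Q,
#' MR-PRESSO (when at least 4 instruments remain) and leave-one-out.  Any
#' stage failure aborts the arm with a stage-named error.
#'
#' @param config list with entries: `exposure`, `outcome`, `disease`
#'   ([summary_stats()] objects or file paths), `exposure_map`/`outcome_map`/
#'   `disease_map` (column maps, needed for paths), `ld` ([ld_matrix()] or LD
#'   table path), and optional tuning keys `p_threshold` (5e-8),
#'   `p_exclusion` (0.05), `r2_threshold` (0.2), `window_kb` (1000),
#'   `palindrome_policy` ("infer"), `eaf_ambiguity` (0.42), `methods`,
#'   `n_boot` (1000), `n_sim` (1000), `seed`.
#' @return An object of class `mr_report`: `stages` (per-stage variant
#'   counts), `fit` ([mr_fit()]), `presso` (or `NULL` with
#'   `presso_skipped_reason`), `loo`, `harmonization_log`, `provenance`.
#' @export
run_mr_arm <- function(config) {
  p_threshold <- config$p_threshold %||% 5e-8
  p_exclusion <- config$p_exclusion %||% 0.05
  r2_threshold <- config$r2_threshold %||% 0.2
  window_kb <- config$window_kb %||% 1000
  policy <- config$palindrome_policy %||% "infer"
  eaf_ambiguity <- config$eaf_ambiguity %||% 0.42
  methods <- config$methods %||% c("ivw_robust", "ivw", "egger_robust",
                                   "egger", "weighted_median")
  n_boot <- config$n_boot %||% 1000
  n_sim <- config$n_sim %||% 1000
  seed <- config$seed %||% 1L

  exposure <- .stage("load_exposure",
    .load_ss(config$exposure, config$exposure_map, "exposure", "quantitative"))
  outcome <- .stage("load_outcome",
    .load_ss(config$outcome, config$outcome_map, "outcome", "binary"))
  disease <- .stage("load_disease",
    .load_ss(config$disease, config$disease_map, "disease", "binary"))
  ld <- .stage("load_ld", if (inherits(config$ld, "ld_matrix")) config$ld
               else read_ld_table(config$ld))

  stages <- list(exposure_records = nrow(exposure))
  sig <- .stage("select_significant", {
    s <- select_significant(exposure, p_threshold)
    if (nrow(s) == 0L) stop("no genome-wide-significant variants")
    s
  })
  stages$significant <- nrow(sig)
  kept <- .stage("exclude_disease_associated", {
    s <- exclude_disease_associated(sig, disease, p_exclusion)
    if (nrow(s) == 0L) stop("every candidate was disease-associated or missing")
    s
  })
  stages$disease_screened <- nrow(kept)
  clumped <- .stage("ld_clump", {
    s <- ld_clump(kept, ld, r2_threshold, window_kb)
    if (nrow(s) == 0L) stop("clumping removed every candidate")
    s
  })
  stages$clumped <- nrow(clumped)
  hset <- .stage("harmonize",
    harmonize(clumped, outcome, palindrome_policy = policy,
              eaf_ambiguity = eaf_ambiguity))
  stages$harmonized <- nrow(hset)

  fit <- .stage("estimation",
    mr_fit(hset, methods = methods, n_boot = n_boot,
           seed = .sub_seed(seed, 21L)))
  presso <- NULL
  presso_skipped <- NULL
  if (nrow(hset) >= 4L) {
    presso <- .stage("mrpresso",
      mr_presso(hset, n_sim = n_sim, seed = .sub_seed(seed, 22L)))
    loo <- .stage("leave_one_out",
      mr_leave_one_out(hset, method = "ivw_robust"))
  } else {
    presso_skipped <- "fewer than 4 instruments"
    loo <- NULL
  }

  structure(list(stages = stages, fit = fit, presso = presso,
                 presso_skipped_reason = presso_skipped, loo = loo,
                 harmonization_log = attr(hset, "harmonization_log"),
                 exclusion_report = attr(kept, "exclusion_report"),
                 provenance = list(seed = seed, n_boot = n_boot,
                                   n_sim = n_sim, p_threshold = p_threshold,
                                   p_exclusion = p_exclusion,
                                   r2_threshold = r2_threshold,
                                   window_kb = window_kb,
                                   palindrome_policy = policy,
                                   eaf_ambiguity = eaf_ambiguity)),
            class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  cat("MR arm report\n")
  cat("Stage counts:",
      paste(sprintf("%s = %d", names(x$stages), unlist(x$stages)),
            collapse = ", "), "\n\n")
  print(x$fit)
  if (!is.null(x$presso)) { cat("\n"); print(x$presso) }
  else if (!is.null(x$presso_skipped_reason))
    cat("\nMR-PRESSO skipped:", x$presso_skipped_reason, "\n")
  invisible(x)
}

#' Run the observational (meta-analysis) arm
#'
#' Pools the study table overall and per outcome, runs subgroup and
#' leave-one-study-out analyses, and the Begg and Egger publication-bias
#' tests (skipped with a reason when fewer than 3 studies are available).
#' Per-outcome failures are isolated and reported, not fatal.
#'
#' @param config list with entries: `studies` (study data frame or TSV path),
#'   optional `label_key` (subgroup column, default `"subgroup"` when
#'   present), optional `outcome_key` (default `"outcome"` when present),
#'   `convert_or_to_rr` (default `FALSE`).
#' @return An object of class `meta_report`: `overall`, `by_outcome`,
#'   `subgroups`, `loo`, `bias` (`egger`, `begg` or skip reasons), `funnel`,
#'   `provenance`.
#' @export
run_meta_arm <- function(config) {
  studies <- .stage("load_studies",
    if (is.data.frame(config$studies)) config$studies
    else read_study_table(config$studies))
  convert <- isTRUE(config$convert_or_to_rr)
  label_key <- config$label_key %||%
    (if ("subgroup" %in% names(studies)) "subgroup" else NULL)
  outcome_key <- config$outcome_key %||%
    (if ("outcome" %in% names(studies)) "outcome" else NULL)

  overall <- .stage("pool_overall", meta_dl_records(studies, convert))
  by_outcome <- NULL
  if (!is.null(outcome_key)) {
    by_outcome <- lapply(split(studies, studies[[outcome_key]]), function(s)
      tryCatch(meta_dl_records(s, convert),
               error = function(e) list(error = conditionMessage(e))))
  }
  subgroups <- if (!is.null(label_key))
    .stage("subgroup_pool", subgroup_pool(studies, label_key, convert))
  else NULL
  loo <- if (nrow(studies) >= 2L)
    .stage("leave_one_study_out", leave_one_study_out(studies, convert))
  else NULL
  bias <- if (nrow(studies) >= 3L) {
    list(egger = .stage("egger_bias_test", egger_bias_test(studies, convert)),
         begg = .stage("begg_bias_test", begg_bias_test(studies, convert)))
  } else list(skipped_reason = "fewer than 3 studies")

  structure(list(overall = overall, by_outcome = by_outcome,
                 subgroups = subgroups, loo = loo, bias = bias,
                 funnel = funnel_table(studies, overall),
                 provenance = list(k_studies = nrow(studies),
                                   convert_or_to_rr = convert)),
            class = "meta_report")
}

#' @export
print.meta_report <- function(x, ...) {
  cat("Meta-analysis arm report\n")
  print(x$overall)
  if (!is.null(x$bias$egger))
    cat(sprintf("Egger bias test: intercept = %.3f, p = %.3g\n",
                x$bias$egger$intercept, x$bias$egger$pvalue))
  if (!is.null(x$bias$begg))
    cat(sprintf("Begg bias test: tau = %.3f, p = %.3g\n",
                x$bias$begg$tau, x$bias$begg$pvalue))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reduce report objects to plain lists/data frames for JSON serialization.
.report_list <- function(x) {
  if (inherits(x, "mr_estimate")) return(unclass(x))
  if (inherits(x, "meta_dl"))
    return(unclass(x)[c("k", "mu", "se", "ci_low", "ci_high", "rr", "rr_low",
                        "rr_high", "pvalue", "Q", "df", "p_Q", "i2_percent",
                        "tau2")])
  if (inherits(x, "mr_fit"))
    return(list(estimates = .mr_fit_table(x),
                egger_intercepts = lapply(x$egger, unclass),
                cochran_q = x$q, n_snps = x$n_snps, seed = x$seed))
  if (inherits(x, "mr_presso"))
    return(list(rss_obs = x$rss_obs, p_global = x$p_global,
                p_adjusted = as.list(x$p_adjusted),
                outliers = x$outliers,
                raw_estimate = unclass(x$raw_estimate),
                corrected_estimate = if (!is.null(x$corrected_estimate))
                  unclass(x$corrected_estimate),
                distortion_pct = x$distortion_pct,
                distortion_pvalue = x$distortion_pvalue,
                skipped_reason = x$skipped_reason,
                n_sim = x$n_sim, seed = x$seed))
  if (is.list(x) && !is.data.frame(x)) return(lapply(x, .report_list))
  x
}

#' Render an analysis report to disk
#'
#' Writes a JSON report (full structure, `digits = NA` so a re-parse
#' reproduces every number) and the main tables as TSV.  Output is
#' deterministic: the same report renders byte-identically.
#'
#' @param report an `mr_report` or `meta_report`.
#' @param dir output directory (created if needed).
#' @param formats subset of `c("json", "tsv")`.
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(report, dir, formats = c("json", "tsv")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  wtsv <- function(df, name) {
    path <- file.path(dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
  }
  body <- .report_list(unclass(report))
  if ("json" %in% formats) {
    path <- file.path(dir, "report.json")
    jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    written <- c(written, path)
  }
  if ("tsv" %in% formats) {
    if (inherits(report, "mr_report")) {
      wtsv(.mr_fit_table(report$fit), "mr_estimates.tsv")
      wtsv(report$harmonization_log, "harmonization_log.tsv")
      if (!is.null(report$loo)) wtsv(report$loo, "leave_one_out.tsv")
    } else if (inherits(report, "meta_report")) {
      ov <- report$overall
      wtsv(data.frame(k = ov$k, rr = ov$rr, rr_low = ov$rr_low,
                      rr_high = ov$rr_high, pvalue = ov$pvalue, Q = ov$Q,
                      p_Q = ov$p_Q, i2_percent = ov$i2_percent,
                      tau2 = ov$tau2), "meta_overall.tsv")
      wtsv(report$funnel, "funnel.tsv")
      if (!is.null(report$loo)) wtsv(report$loo, "leave_one_study_out.tsv")
    }
  }
  invisible(written)
}
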
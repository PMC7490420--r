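# Reading, validating and writing GWAS summary statistics and LD tables.

.canonical_cols <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                     "eaf", "beta", "se", "pvalue", "n")
.required_cols <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pvalue")

# Per-row validity check; returns "" for valid rows, else a reason label.
.snp_row_problems <- function(df) {
  reason <- rep("", nrow(df))
  bad <- is.na(df$rsid) | df$rsid == ""
  reason[bad & reason == ""] <- "missing_rsid"
  bad <- is.na(df$effect_allele) | is.na(df$other_allele) |
    df$effect_allele == "" | df$other_allele == ""
  reason[bad & reason == ""] <- "missing_allele"
  bad <- !is.na(df$effect_allele) & !is.na(df$other_allele) &
    df$effect_allele == df$other_allele
  reason[bad & reason == ""] <- "identical_alleles"
  bad <- !is.finite(df$beta)
  reason[bad & reason == ""] <- "nonfinite_beta"
  bad <- !is.finite(df$se) | df$se <= 0
  reason[bad & reason == ""] <- "nonpositive_se"
  bad <- !is.finite(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1
  reason[bad & reason == ""] <- "bad_pvalue"
  bad <- !is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1)
  reason[bad & reason == ""] <- "bad_eaf"
  reason
}

#' Construct a set of GWAS summary statistics
#'
#' A `summary_stats` object is a data frame with one row per variant and the
#' canonical columns `rsid`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#' `eaf`, `beta`, `se`, `pvalue`, `n`.  `beta` is the per-allele effect on the
#' trait scale (log-odds for binary traits), `eaf` the effect-allele frequency
#' (may be `NA`).  Optional columns absent from `x` are filled with `NA`.
#'
#' @param x data frame carrying at least `rsid`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pvalue`.
#' @param trait_id label of the GWAS this set came from.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param unit free-text unit of `beta` (e.g. `"mmol/L"`, `"log-odds"`).
#' @return A `summary_stats` data frame.  Invalid rows are an error here; use
#'   [read_summary_stats()] for drop-and-report loading.
#' @export
summary_stats <- function(x, trait_id,
                          trait_type = c("quantitative", "binary"),
                          unit = NA_character_) {
  trait_type <- match.arg(trait_type)
  x <- as.data.frame(x)
  missing_req <- setdiff(.required_cols, names(x))
  if (length(missing_req))
    stop("missing required column(s): ", paste(missing_req, collapse = ", "))
  if (!"chrom" %in% names(x)) x$chrom <- NA_character_
  if (!"pos" %in% names(x)) x$pos <- NA_real_
  if (!"eaf" %in% names(x)) x$eaf <- NA_real_
  if (!"n" %in% names(x)) x$n <- NA_real_
  x <- x[, .canonical_cols]
  x$rsid <- as.character(x$rsid)
  x$chrom <- as.character(x$chrom)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (cl in c("pos", "eaf", "beta", "se", "pvalue", "n"))
    x[[cl]] <- as.numeric(x[[cl]])
  problems <- .snp_row_problems(x)
  if (any(problems != ""))
    stop("invalid summary-statistic row(s): ",
         paste(unique(problems[problems != ""]), collapse = ", "))
  if (anyDuplicated(x$rsid))
    stop("duplicate rsid(s) in summary-statistic set")
  rownames(x) <- NULL
  structure(x, class = c("summary_stats", "data.frame"),
            trait_id = trait_id, trait_type = trait_type, unit = unit)
}

# Subset a summary_stats object preserving its metadata attributes.
.subset_ss <- function(x, idx) {
  out <- as.data.frame(x)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("summary_stats", "data.frame"),
            trait_id = attr(x, "trait_id"),
            trait_type = attr(x, "trait_type"),
            unit = attr(x, "unit"))
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s), %d variant(s)\n",
              attr(x, "trait_id"), attr(x, "trait_type"), nrow(x)))
  print(head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Column-mapping presets for common summary-statistics dialects
#'
#' Public GWAS files use heterogeneous headers; a column map names, for each
#' canonical field, the column holding it in a given file.  Presets cover the
#' dialects of glycaemic-trait (MAGIC-style), coronary (CARDIoGRAM-style) and
#' kidney (CKDGen-style) consortium files.
#'
#' @param style one of `"magic"`, `"cardiogram"`, `"ckdgen"`.
#' @return Named character vector mapping canonical names to file columns.
#' @export
sumstats_column_preset <- function(style = c("magic", "cardiogram", "ckdgen")) {
  style <- match.arg(style)
  switch(style,
    magic = c(rsid = "snp", effect_allele = "effect_allele",
              other_allele = "other_allele", eaf = "maf",
              beta = "effect", se = "stderr", pvalue = "pvalue"),
    cardiogram = c(rsid = "markername", chrom = "chr", pos = "bp_hg19",
                   effect_allele = "effect_allele",
                   other_allele = "noneffect_allele",
                   eaf = "effect_allele_freq", beta = "beta",
                   se = "se_dgc", pvalue = "p_dgc"),
    ckdgen = c(rsid = "RSID", chrom = "Chr", pos = "Pos_b37",
               effect_allele = "Allele1", other_allele = "Allele2",
               eaf = "Freq1", beta = "Effect", se = "StdErr",
               pvalue = "P-value", n = "n_total_sum"))
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a (optionally gzip-compressed) tab- or whitespace-delimited file with
#' a header row, maps its columns to the canonical schema, uppercases alleles,
#' drops rows violating record invariants (counting them by reason), and
#' resolves duplicate rsids by keeping the smallest p-value.
#'
#' @param path file path; `.gz` handled transparently.
#' @param column_map named vector/list mapping canonical names
#'   (`rsid`, `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`,
#'   optionally `chrom`, `pos`, `eaf`, `n`) to file column names.  See
#'   [sumstats_column_preset()].
#' @param trait_id,trait_type,unit passed to [summary_stats()].
#' @return A `summary_stats` object with a `"load_report"` attribute listing
#'   rows read, dropped (by reason) and duplicates collapsed.
#' @export
read_summary_stats <- function(path, column_map, trait_id,
                               trait_type = c("quantitative", "binary"),
                               unit = NA_character_) {
  trait_type <- match.arg(trait_type)
  column_map <- unlist(column_map)
  missing_req <- setdiff(.required_cols, names(column_map))
  if (length(missing_req))
    stop("column_map must name column(s): ", paste(missing_req, collapse = ", "))
  open_con <- function() if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  # tab-delimited first (tolerates empty fields); whitespace as fallback
  raw <- read.table(open_con(), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", quote = "\"")
  if (ncol(raw) == 1L)
    raw <- read.table(open_con(), header = TRUE, sep = "",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      comment.char = "", quote = "\"")
  absent <- setdiff(unname(column_map), names(raw))
  if (length(absent))
    stop("mapped column(s) not found in ", path, ": ",
         paste(absent, collapse = ", "))
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in .canonical_cols) {
    df[[canon]] <- if (canon %in% names(column_map)) raw[[column_map[[canon]]]]
                   else NA
  }
  df$rsid <- as.character(df$rsid)
  df$chrom <- as.character(df$chrom)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (cl in c("pos", "eaf", "beta", "se", "pvalue", "n"))
    df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))

  problems <- .snp_row_problems(df)
  dropped <- table(problems[problems != ""])
  df <- df[problems == "", , drop = FALSE]
  # duplicate rsids: keep the record with the smallest p-value, then restore
  # the original file order of the survivors
  idx <- order(df$pvalue, seq_len(nrow(df)))
  keep_idx <- idx[!duplicated(df$rsid[idx])]
  n_dup <- nrow(df) - length(keep_idx)
  df <- df[sort(keep_idx), , drop = FALSE]
  if (nrow(df) == 0L)
    stop("no valid summary-statistic rows in ", path)
  out <- summary_stats(df, trait_id = trait_id, trait_type = trait_type,
                       unit = unit)
  attr(out, "load_report") <- list(
    path = path, n_rows_read = nrow(raw),
    n_dropped = sum(problems != ""),
    dropped_by_reason = as.list(dropped),
    n_duplicates_collapsed = n_dup, n_records = nrow(out))
  out
}

#' Write summary statistics as canonical tab-delimited text
#'
#' The canonical header is `rsid chrom pos effect_allele other_allele eaf beta
#' se pvalue n`; numeric fields are written with 17 significant digits so a
#' write/read round trip preserves values.
#'
#' @param set a `summary_stats` object.
#' @param path output path; `.gz` writes gzip-compressed text.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(set, path) {
  stopifnot(inherits(set, "summary_stats"))
  df <- as.data.frame(set)
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  for (cl in c("pos", "eaf", "beta", "se", "pvalue", "n"))
    df[[cl]] <- fmt(df[[cl]])
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Is an allele pair palindromic?
#'
#' A variant is palindromic when its two alleles are strand complements of
#' each other ({A,T} or {C,G}), so strand orientation cannot be resolved from
#' the alleles alone.  Indels and non-ACGT codes are classified
#' non-palindromic (palindromy is defined only for single-base complements).
#'
#' @param effect_allele,other_allele character vectors of alleles.
#' @return Logical vector.
#' @export
classify_palindromic <- function(effect_allele, other_allele) {
  a <- toupper(effect_allele)
  b <- toupper(other_allele)
  simple <- nchar(a) == 1L & nchar(b) == 1L & a %in% c("A", "C", "G", "T") &
    b %in% c("A", "C", "G", "T")
  out <- simple & ((a == "A" & b == "T") | (a == "T" & b == "A") |
                   (a == "C" & b == "G") | (a == "G" & b == "C"))
  out & a != b
}

# Single-base strand complement; NA for indels / non-ACGT codes.
.complement <- function(x) {
  simple <- nchar(x) == 1L & x %in% c("A", "C", "G", "T")
  out <- rep(NA_character_, length(x))
  out[simple] <- chartr("ACGT", "TGCA", x[simple])
  out
}

#' Construct a pairwise LD matrix
#'
#' @param r2 square numeric matrix of squared correlations; symmetric, unit
#'   diagonal, entries in `[0, 1]`.
#' @param rsids optional variant identifiers used as dimnames.
#' @return An `ld_matrix` (a validated matrix with variant dimnames).
#' @export
ld_matrix <- function(r2, rsids = NULL) {
  r2 <- as.matrix(r2)
  if (nrow(r2) != ncol(r2)) stop("r2 must be square")
  if (!is.null(rsids)) dimnames(r2) <- list(rsids, rsids)
  if (is.null(rownames(r2))) stop("ld_matrix needs variant identifiers")
  if (max(abs(r2 - t(r2))) > 1e-8) stop("r2 must be symmetric")
  if (max(abs(diag(r2) - 1)) > 1e-8) stop("r2 diagonal must be 1")
  if (min(r2) < -1e-12 || max(r2) > 1 + 1e-12) stop("r2 entries must lie in [0, 1]")
  r2[r2 < 0] <- 0
  r2[r2 > 1] <- 1
  structure(r2, class = c("ld_matrix", "matrix", "array"))
}

#' Read an LD table
#'
#' Accepts either a long 3-column file (`rsid_a`, `rsid_b`, `r2`; unlisted
#' pairs are taken as r2 = 0) or a dense matrix file whose first column holds
#' the variant identifiers.
#'
#' @param path tab-delimited text file with header.
#' @param rsids optional identifiers fixing the matrix order (long format
#'   only); defaults to the identifiers present in the file.
#' @return An [ld_matrix()].
#' @export
read_ld_table <- function(path, rsids = NULL) {
  tab <- read.table(path, header = TRUE, sep = "", stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (ncol(tab) == 3L) {
    a <- as.character(tab[[1L]]); b <- as.character(tab[[2L]])
    r2 <- as.numeric(tab[[3L]])
    ids <- if (is.null(rsids)) sort(unique(c(a, b))) else rsids
    m <- diag(1, length(ids))
    dimnames(m) <- list(ids, ids)
    keep <- a %in% ids & b %in% ids
    m[cbind(a[keep], b[keep])] <- r2[keep]
    m[cbind(b[keep], a[keep])] <- r2[keep]
    ld_matrix(m)
  } else {
    ids <- as.character(tab[[1L]])
    m <- as.matrix(tab[, -1L, drop = FALSE])
    ld_matrix(m, rsids = ids)
  }
}
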
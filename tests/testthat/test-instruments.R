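test_that("significance filtering is strict and recovers planted instruments", {
  ss <- summary_stats(data.frame(
    rsid = c("a", "b", "c"), effect_allele = "A", other_allele = "G",
    beta = 0.1, se = 0.01, pvalue = c(4e-8, 5e-8, 6e-8)), "x")
  expect_equal(select_significant(ss)$rsid, "a")
  ss$pvalue <- rep(1, 3)
  expect_equal(nrow(select_significant(summary_stats(ss, "x"))), 0L)
  d <- gen_mr_dataset(n_snps = 40, n_null_snps = 960, seed = 77)
  sig <- select_significant(d$exposure)
  expect_setequal(sig$rsid, d$truth$snps$rsid)
})

test_that("disease-association exclusion uses a strict threshold and drops unmatched variants", {
  cand <- summary_stats(data.frame(
    rsid = c("a", "b", "c"), effect_allele = "A", other_allele = "G",
    beta = 0.1, se = 0.01, pvalue = 1e-9), "x")
  dis <- summary_stats(data.frame(
    rsid = c("a", "b"), effect_allele = "A", other_allele = "G",
    beta = 0, se = 0.01, pvalue = c(0.04, 0.06)), "t2d")
  kept <- exclude_disease_associated(cand, dis)
  expect_equal(kept$rsid, "b")
  rep <- attr(kept, "exclusion_report")
  expect_equal(rep$excluded_rsids, "a")
  expect_equal(rep$missing_rsids, "c")

  d <- gen_mr_dataset(n_snps = 30, disease_assoc_indices = 1:5, seed = 8)
  kept <- exclude_disease_associated(d$exposure, d$disease)
  # every planted association is excluded; survivors are exactly the
  # candidates whose disease p exceeds the threshold
  expect_false(any(d$truth$snps$rsid[1:5] %in% kept$rsid))
  expect_setequal(kept$rsid, d$disease$rsid[d$disease$pvalue > 0.05])
})

test_that("greedy clumping keeps the best variant and respects the window", {
  ss <- summary_stats(data.frame(
    rsid = c("A", "B", "C"), chrom = "1", pos = c(1e6, 1.2e6, 1.4e6),
    effect_allele = "A", other_allele = "G", beta = 0.1, se = 0.01,
    pvalue = c(1e-10, 1e-9, 1e-8)), "x")
  r2 <- diag(1, 3); dimnames(r2) <- list(c("A", "B", "C"), c("A", "B", "C"))
  r2["A", "B"] <- r2["B", "A"] <- 0.5
  r2["A", "C"] <- r2["C", "A"] <- 0.05
  out <- ld_clump(ss, ld_matrix(r2))
  expect_setequal(out$rsid, c("A", "C"))

  # outside the window high r2 does not clump
  far <- summary_stats(data.frame(
    rsid = c("A", "B"), chrom = "1", pos = c(1e6, 2.5e6),
    effect_allele = "A", other_allele = "G", beta = 0.1, se = 0.01,
    pvalue = c(1e-10, 1e-9)), "x")
  r2 <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_setequal(ld_clump(far, ld_matrix(r2))$rsid, c("A", "B"))

  # cross-chromosome pairs never clump regardless of r2 entries
  cross <- summary_stats(data.frame(
    rsid = c("A", "B"), chrom = c("1", "2"), pos = c(1e6, 1.1e6),
    effect_allele = "A", other_allele = "G", beta = 0.1, se = 0.01,
    pvalue = c(1e-10, 1e-9)), "x")
  expect_setequal(ld_clump(cross, ld_matrix(r2))$rsid, c("A", "B"))
})

test_that("clump output is order-independent and verified by brute force", {
  d <- gen_mr_dataset(n_snps = 50, ld_block_size = 5, ld_r2_within = 0.5,
                      seed = 13)
  out <- ld_clump(d$exposure, d$ld)
  # brute force: no retained pair within window violates the threshold
  df <- as.data.frame(out)
  for (i in seq_len(nrow(df))) for (j in seq_len(nrow(df))) {
    if (i >= j) next
    if (df$chrom[i] == df$chrom[j] &&
        abs(df$pos[i] - df$pos[j]) <= 1e6)
      expect_lt(d$ld[df$rsid[i], df$rsid[j]], 0.2)
  }
  # every removed variant conflicts with a retained, better-ranked one
  rep <- attr(out, "clump_report")
  removed <- rep[!rep$kept, ]
  full <- as.data.frame(d$exposure)
  for (r in seq_len(nrow(removed))) {
    winner <- removed$removed_by[r]
    expect_true(winner %in% df$rsid)
    pr <- full$pvalue[full$rsid == removed$rsid[r]]
    pw <- full$pvalue[full$rsid == winner]
    expect_true(pw < pr || (pw == pr && winner < removed$rsid[r]))
  }
  # permuted input gives the same retained set
  set.seed(1)
  perm <- summary_stats(as.data.frame(d$exposure)[sample(50), ], "x")
  expect_setequal(ld_clump(perm, d$ld)$rsid, out$rsid)
})

test_that("harmonization handles swaps, complements and palindromes as specified", {
  ex <- summary_stats(data.frame(
    rsid = c("r1", "r2", "r3", "r4", "r5", "r6"),
    effect_allele = c("A", "A", "A", "A", "A", "A"),
    other_allele = c("G", "G", "G", "T", "T", "G"),
    eaf = c(0.3, 0.3, 0.3, 0.3, 0.50, 0.3),
    beta = c(0.10, 0.10, 0.10, 0.10, 0.10, 0.10),
    se = 0.01, pvalue = 1e-9), "fg")
  ou <- summary_stats(data.frame(
    rsid = c("r1", "r2", "r3", "r4", "r5", "r6"),
    effect_allele = c("G", "T", "C", "T", "A", "A"),
    other_allele = c("A", "C", "T", "A", "T", "C"),
    eaf = c(0.7, 0.3, 0.7, 0.7, 0.5, 0.3),
    beta = c(-0.05, 0.05, -0.05, -0.05, 0.05, 0.05),
    se = 0.01, pvalue = 0.5), "cad")
  h <- harmonize(ex, ou, palindrome_policy = "infer")
  log <- attr(h, "harmonization_log")
  act <- setNames(log$action, log$rsid)
  # r1: swapped alleles -> sign flip
  expect_equal(act[["r1"]], "sign_flipped")
  expect_equal(h$Gamma[h$rsid == "r1"], 0.05)
  # r2: strand complements (A/G vs T/C) -> kept as-is
  expect_equal(act[["r2"]], "kept")
  expect_equal(h$Gamma[h$rsid == "r2"], 0.05)
  # r3: swapped complements -> sign flip
  expect_equal(act[["r3"]], "sign_flipped")
  expect_equal(h$Gamma[h$rsid == "r3"], 0.05)
  # r4: palindromic, frequencies on opposite sides -> aligned by flipping
  expect_equal(act[["r4"]], "palindrome_aligned")
  expect_equal(h$Gamma[h$rsid == "r4"], 0.05)
  # r5: palindromic with ambiguous frequency -> dropped
  expect_equal(act[["r5"]], "dropped_palindrome")
  # r6: irreconcilable alleles -> dropped
  expect_equal(act[["r6"]], "dropped_mismatch")
  expect_false(any(c("r5", "r6") %in% h$rsid))

  # drop policy removes all palindromic variants
  h2 <- harmonize(ex, ou, palindrome_policy = "drop")
  log2 <- attr(h2, "harmonization_log")
  expect_equal(sort(log2$rsid[log2$action == "dropped_palindrome"]),
               c("r4", "r5"))

  # missing from outcome
  ex2 <- summary_stats(rbind(as.data.frame(ex),
    data.frame(rsid = "r9", effect_allele = "A", other_allele = "G",
               eaf = 0.2, beta = 0.1, se = 0.01, pvalue = 1e-9,
               chrom = NA_character_, pos = NA_real_, n = NA_real_)), "fg")
  log3 <- attr(harmonize(ex2, ou), "harmonization_log")
  expect_equal(log3$action[log3$rsid == "r9"], "dropped_missing")
})

test_that("harmonization orients exposure effects positive and is idempotent", {
  d <- gen_mr_dataset(n_snps = 20, frac_palindromic = 0.2,
                      frac_strand_flip = 0.3, frac_allele_swap = 0.3,
                      maf_range = c(0.1, 0.4), seed = 5)
  h <- harmonize(d$exposure, d$outcome)
  expect_true(all(h$gamma > 0))
  # idempotence: re-harmonizing the harmonized pair changes nothing
  as_ss <- function(h, beta, se, id) summary_stats(data.frame(
    rsid = h$rsid, chrom = h$chrom, pos = h$pos,
    effect_allele = h$effect_allele, other_allele = h$other_allele,
    eaf = h$eaf_x, beta = beta, se = se,
    pvalue = pmax(2 * pnorm(-abs(beta / se)), 1e-300)), id)
  ex2 <- as_ss(h, h$gamma, h$se_x, "fg")
  ou2 <- as_ss(h, h$Gamma, h$se_y, "cad")
  h2 <- harmonize(ex2, ou2)
  expect_equal(h2$gamma, h$gamma)
  expect_equal(h2$Gamma, h$Gamma)
  expect_true(all(attr(h2, "harmonization_log")$action %in%
                    c("kept", "palindrome_aligned")))
})

test_that("flipping an input record's alleles and sign leaves the harmonized pair invariant", {
  d <- gen_mr_dataset(n_snps = 10, seed = 21)
  h1 <- harmonize(d$exposure, d$outcome)
  flipped <- as.data.frame(d$outcome)
  i <- 4
  tmp <- flipped$effect_allele[i]
  flipped$effect_allele[i] <- flipped$other_allele[i]
  flipped$other_allele[i] <- tmp
  flipped$beta[i] <- -flipped$beta[i]
  flipped$eaf[i] <- 1 - flipped$eaf[i]
  h2 <- harmonize(d$exposure, summary_stats(flipped, "outcome_synth"))
  expect_equal(h2$gamma, h1$gamma)
  expect_equal(h2$Gamma, h1$Gamma)
})

test_that("harmonization recovers pre-corruption effects from a corrupted outcome", {
  d <- gen_mr_dataset(n_snps = 30, frac_strand_flip = 0.2,
                      frac_allele_swap = 0.2, frac_palindromic = 0.2,
                      maf_range = c(0.1, 0.4), seed = 31)
  h <- harmonize(d$exposure, d$outcome)
  tr <- d$truth$snps
  expect_setequal(h$rsid, tr$rsid)   # nothing ambiguous at these frequencies
  m <- match(h$rsid, tr$rsid)
  expect_equal(h$gamma, tr$gamma_obs_oriented[m], tolerance = 1e-12)
  expect_equal(h$Gamma, tr$Gamma_obs_oriented[m], tolerance = 1e-12)
})

test_that("harmonization fails loudly when nothing survives", {
  ex <- summary_stats(data.frame(
    rsid = "r1", effect_allele = "A", other_allele = "G",
    beta = 0.1, se = 0.01, pvalue = 1e-9), "fg")
  ou <- summary_stats(data.frame(
    rsid = "r2", effect_allele = "A", other_allele = "G",
    beta = 0.1, se = 0.01, pvalue = 0.5), "cad")
  expect_error(harmonize(ex, ou), "harmonize")
})
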
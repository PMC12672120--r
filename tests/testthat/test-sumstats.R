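test_that("summary statistics round-trip through TSV exactly", {
  s <- toy_sumstats(beta = c(0.123456789012345, -1e-7, 2.5),
                    pval = c(1e-300, 0.5, 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(s, path)
  s2 <- read_sumstats(path, trait_id = "trait", trait_type = "continuous")
  expect_equal(s2$records, s$records)
  expect_equal(s2$trait_id, s$trait_id)
})

test_that("missing eaf serializes as NA and is re-read as missing", {
  s <- toy_sumstats(eaf = c(NA, 0.3, 0.4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(s, path)
  s2 <- read_sumstats(path, trait_id = "trait")
  expect_true(is.na(s2$records$eaf[1]))
  expect_equal(s2$records$eaf[2:3], c(0.3, 0.4))
})

test_that("empty record set writes a header-only file", {
  s <- toy_sumstats()
  s$records <- s$records[0, ]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(s, path)
  expect_length(readLines(path), 1L)
  expect_equal(nrow(read_sumstats(path, "t")$records), 0L)
})

test_that("rows violating record invariants are rejected with a count", {
  df <- toy_records(3)
  df$se[2] <- 0
  expect_warning(s <- sumstats(df, "t"), "rejected")
  expect_equal(nrow(s$records), 2L)
  expect_false("rs2" %in% s$records$variant_id)

  # each invariant individually
  for (mut in list(function(d) { d$eaf[1] <- 1.2; d },
                   function(d) { d$pos[1] <- 0; d },
                   function(d) { d$other_allele[1] <- "A"; d },
                   function(d) { d$pval[1] <- 0; d })) {
    expect_warning(s <- sumstats(mut(toy_records(3)), "t"), "rejected")
    expect_equal(nrow(s$records), 2L)
  }
})

test_that("missing mandatory column is a format error naming the column", {
  df <- toy_records(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df[setdiff(names(df), "se")], path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(read_sumstats(path, "t"), "se")
})

test_that("column remapping resolves non-standard headers", {
  df <- toy_records(3)
  names(df)[names(df) == "variant_id"] <- "SNP"
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  s <- read_sumstats(path, "t", col_map = c(variant_id = "SNP"))
  expect_equal(s$records$variant_id, paste0("rs", 1:3))
})

test_that("non-numeric beta reports the offending variant", {
  df <- toy_records(3)
  df$beta <- as.character(df$beta)
  df$beta[2] <- "abc"
  expect_error(sumstats(df, "t"), "rs2")
})

test_that("duplicate variant ids are rejected", {
  df <- toy_records(3)
  df$variant_id[2] <- "rs1"
  expect_error(sumstats(df, "t"), "duplicate")
})

test_that("harmonization keeps, flips and drops variants correctly", {
  ex <- toy_sumstats(5, ea = c("A", "A", "T", "A", "A"),
                     oa = c("G", "G", "C", "T", "T"),
                     eaf = c(0.3, 0.3, 0.3, 0.50, 0.2),
                     trait_id = "exp")
  ou <- toy_sumstats(5, ea = c("A", "G", "A", "A", "A"),
                     oa = c("G", "A", "G", "T", "T"),
                     beta = rep(0.2, 5), eaf = c(0.3, 0.3, 0.3, 0.50, 0.2),
                     trait_id = "out")
  h <- harmonize(ex, ou)
  r <- h$rows[match(paste0("rs", 1:5), h$rows$variant_id), ]
  # identical alleles: kept unchanged
  expect_equal(r$action[1], "kept")
  expect_equal(r$beta_out[1], 0.2)
  # swapped alleles: sign and frequency flipped
  expect_equal(r$action[2], "flipped")
  expect_equal(r$beta_out[2], -0.2)
  expect_equal(r$eaf_out[2], 0.7)
  # strand complement (exposure T/C, outcome A/G): kept after complementing
  expect_equal(r$action[3], "kept")
  expect_equal(r$beta_out[3], 0.2)
  # palindromic with ambiguous frequency: dropped
  expect_equal(r$action[4], "dropped_palindromic")
  expect_true(is.na(r$beta_out[4]))
  # palindromic, both frequencies unambiguous and on the same side: kept
  expect_equal(r$action[5], "kept")
})

test_that("palindromic variants with opposite-side frequencies are flipped", {
  ex <- toy_sumstats(1, ea = "A", oa = "T", eaf = 0.2, trait_id = "exp")
  ou <- toy_sumstats(1, ea = "A", oa = "T", beta = 0.2, eaf = 0.8,
                     trait_id = "out")
  h <- harmonize(ex, ou)
  expect_equal(h$rows$action, "flipped")
  expect_equal(h$rows$beta_out, -0.2)
  expect_equal(h$rows$eaf_out, 0.2)
})

test_that("palindromic variants with missing eaf are dropped", {
  ex <- toy_sumstats(1, ea = "A", oa = "T", eaf = NA, trait_id = "exp")
  ou <- toy_sumstats(1, ea = "A", oa = "T", eaf = 0.2, trait_id = "out")
  expect_equal(harmonize(ex, ou)$rows$action, "dropped_palindromic")
})

test_that("empty variant intersection is a harmonization error", {
  ex <- toy_sumstats(2, trait_id = "exp")
  ou <- toy_sumstats(2, trait_id = "out")
  ou$records$variant_id <- c("rsX", "rsY")
  expect_error(harmonize(ex, ou), "no shared variants")
})

test_that("harmonization is idempotent on an aligned pair", {
  sim <- simulate_triple(sim_config(seed = 7))
  h1 <- harmonize(sim$exposure, sim$outcome)
  # rebuild an outcome set already aligned to the exposure coding
  aligned <- sim$outcome
  idx <- match(h1$rows$variant_id, aligned$records$variant_id)
  aligned$records$beta[idx] <- h1$rows$beta_out
  aligned$records$eaf[idx] <- h1$rows$eaf_out
  aligned$records$effect_allele <- sim$exposure$records$effect_allele
  aligned$records$other_allele <- sim$exposure$records$other_allele
  h2 <- harmonize(sim$exposure, aligned)
  expect_equal(h2$rows$beta_out, h1$rows$beta_out)
  expect_true(all(h2$rows$action == "kept"))
})

test_that("downstream estimates are invariant to allele-coding flips", {
  sim <- simulate_triple(sim_config(seed = 11, beta1_true = 0.2,
                                    beta2_true = 0.5, direct_true = 0.1))
  base <- mr_ivw(harmonize(sim$exposure, sim$outcome), model = "fixed")
  # recode every outcome variant to the opposite effect allele
  flipped <- sim$outcome
  rec <- flipped$records
  tmp <- rec$effect_allele
  rec$effect_allele <- rec$other_allele
  rec$other_allele <- tmp
  rec$beta <- -rec$beta
  rec$eaf <- 1 - rec$eaf
  flipped$records <- rec
  est <- mr_ivw(harmonize(sim$exposure, flipped), model = "fixed")
  expect_equal(est$beta, base$beta, tolerance = 1e-12)
  expect_equal(est$se, base$se, tolerance = 1e-12)
})

test_that("genomic control matches hand arithmetic and floors at 1", {
  # single record with z = 1: lambda = 1/median(chi2_1)
  s <- toy_sumstats(1, beta = 1, se = 1, pval = 0.317)
  adj <- genomic_control_adjust(s)
  expect_equal(adj$lambda_gc, 2.198109, tolerance = 1e-6)
  expect_equal(adj$sumstats$records$se, 1.482602, tolerance = 1e-6)
  expect_equal(adj$sumstats$records$pval,
               2 * pnorm(-abs(1 / 1.482602219)), tolerance = 1e-6)

  # all z^2 at the chi-square median: unchanged
  z0 <- sqrt(qchisq(0.5, 1))
  s2 <- toy_sumstats(3, beta = rep(z0, 3), se = rep(1, 3))
  adj2 <- genomic_control_adjust(s2)
  expect_equal(adj2$lambda_gc, 1)
  expect_equal(adj2$sumstats$records, s2$records)

  # deflation scenario: returned unchanged
  s3 <- toy_sumstats(3, beta = rep(0.1, 3), se = rep(1, 3), pval = rep(0.9, 3))
  adj3 <- genomic_control_adjust(s3)
  expect_lt(adj3$lambda_gc, 1)
  expect_equal(adj3$sumstats$records, s3$records)
})

test_that("genomic control never decreases SEs and deflates the median chi2", {
  set.seed(5)
  for (i in 1:5) {
    s <- toy_sumstats(50, beta = rnorm(50, 0, 2), se = runif(50, 0.5, 1.5),
                      pval = runif(50, 1e-4, 1), pos = 1:50 * 100)
    adj <- genomic_control_adjust(s)
    expect_true(all(adj$sumstats$records$se >= s$records$se))
    if (adj$lambda_gc > 1) {
      z2 <- (adj$sumstats$records$beta / adj$sumstats$records$se)^2
      expect_lte(median(z2), qchisq(0.5, 1) * (1 + 1e-8))
    }
  }
})
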
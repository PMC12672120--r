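# In-code fixtures shared across test files.

# minimal well-formed summary-statistic table
toy_records <- function(n = 3, beta = seq(0.1, by = 0.1, length.out = n),
                        se = rep(0.05, n), eaf = rep(0.3, n),
                        pval = rep(1e-10, n), nsample = 10000,
                        chrom = "1", pos = seq(1000, by = 1000, length.out = n),
                        ea = rep("A", n), oa = rep("G", n)) {
  data.frame(variant_id = paste0("rs", seq_len(n)), chrom = chrom, pos = pos,
             effect_allele = ea, other_allele = oa, beta = beta, se = se,
             eaf = eaf, pval = pval, n = nsample, stringsAsFactors = FALSE)
}

toy_sumstats <- function(..., trait_id = "trait", trait_type = "continuous") {
  sumstats(toy_records(...), trait_id = trait_id, trait_type = trait_type)
}

# build a harmonized pair directly from effect vectors (all rows kept)
make_pair <- function(bx, sx, by, sy, ids = paste0("rs", seq_along(bx)),
                      eaf = rep(0.3, length(bx)), n_exp = 10000,
                      n_out = 50000) {
  rows <- data.frame(variant_id = ids, beta_exp = bx, se_exp = sx,
                     eaf_exp = eaf, pval_exp = 2 * pnorm(-abs(bx / sx)),
                     n_exp = n_exp, beta_out = by, se_out = sy,
                     eaf_out = eaf, n_out = n_out, action = "kept",
                     stringsAsFactors = FALSE)
  structure(list(exposure_id = "exp", outcome_id = "out", rows = rows),
            class = "harmonized_pair")
}

# random instrument set for oracle-equivalence loops
random_pair <- function(k, seed) {
  set.seed(seed)
  bx <- runif(k, 0.05, 0.5) * sample(c(-1, 1), k, replace = TRUE)
  sx <- runif(k, 0.01, 0.05)
  by <- bx * 0.2 + rnorm(k, 0, 0.05)
  sy <- runif(k, 0.02, 0.1)
  make_pair(bx, sx, by, sy)
}

# five toy rows: one violating each filter plus one passing all
filter_toy <- function() {
  region <- gene_region("g", "1", 2000000, 3000000)
  df <- data.frame(
    variant_id = c("fail_p", "fail_maf", "fail_f", "fail_cis", "pass"),
    chrom = "1",
    pos = c(2500000, 2500000, 2500000, 999999, 2500000),  # fail_cis < start - 1e6
    effect_allele = "A", other_allele = "G",
    beta = c(0.2, 0.2, 0.01, 0.2, 0.2),                   # fail_f: tiny effect
    se = 0.02,
    eaf = c(0.3, 0.005, 0.3, 0.3, 0.3),                   # fail_maf below 0.01
    pval = c(1e-6, 1e-10, 1e-10, 1e-10, 1e-10),           # fail_p above 5e-8
    n = 31684, stringsAsFactors = FALSE)
  list(s = sumstats(df, "exp"), region = region)
}

# instrument set + LD matrix for clumping tests
clump_toy <- function(pvals, pos = c(1000, 2000, 3000, 4000),
                      r = diag(length(pvals))) {
  n <- length(pvals)
  s <- toy_sumstats(n, beta = rep(0.2, n), se = rep(0.02, n),
                    pval = pvals, pos = pos, nsample = 31684)
  inst <- select_instruments(s, pval_max = 1, maf_min = 0, f_min = 0)
  list(inst = inst, ld = ld_matrix(r, paste0("rs", seq_len(n))))
}

# independent re-derivation of greedy clumping, written from the definition
greedy_clump_oracle <- function(df, r2mat, r2_max, window_bp) {
  kept <- character(0)
  pool <- df
  while (nrow(pool) > 0) {
    best <- pool[order(pool$pval, -pool$f_stat, pool$variant_id)[1], ]
    kept <- c(kept, best$variant_id)
    pool <- pool[pool$variant_id != best$variant_id, , drop = FALSE]
    if (nrow(pool) > 0) {
      drop <- sapply(seq_len(nrow(pool)), function(i) {
        pool$chrom[i] == best$chrom &&
          abs(pool$pos[i] - best$pos) <= window_bp &&
          r2mat[pool$variant_id[i], best$variant_id]^2 >= r2_max
      })
      pool <- pool[!drop, , drop = FALSE]
    }
  }
  kept
}

# tighter ratio spread, keeping the 512-point mode grid below 1e-3 spacing
random_tight_pair <- function(k, seed) {
  set.seed(seed)
  bx <- runif(k, 0.3, 0.6)
  sx <- runif(k, 0.005, 0.02)
  by <- bx * 0.2 + rnorm(k, 0, 0.02)
  sy <- runif(k, 0.01, 0.03)
  make_pair(bx, sx, by, sy)
}
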
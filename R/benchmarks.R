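# Seeded calibration benchmarks: each runs the full pipeline (simulate,
# select, clump, harmonize, estimate) many times against known truth.
# One master seed fans out to per-replicate seeds below 2^31.

bench_seed <- function(seed, offset, i) (seed %% 1000L) * 1000000L + offset + i

# simulate -> select -> clump -> harmonize for one replicate
sim_pair <- function(cfg) {
  sim <- simulate_triple(cfg)
  inst <- suppressWarnings(select_instruments(sim$exposure,
                                              region = sim$region))
  if (nrow(inst$rows) < 2) return(NULL)
  inst <- ld_clump(inst, sim$ld)
  ex <- subset_to_instruments(sim$exposure, inst)
  list(pair = harmonize(ex, sim$outcome), inst = inst, sim = sim)
}

#' Type-I error and p-value calibration of IVW under the null
#'
#' Simulates null triples (no causal effects, no pleiotropy) under the
#' default study regimes, runs instrument selection, clumping, harmonization
#' and the fixed-effect IVW test in each, and summarizes the empirical
#' rejection rate at the 5% level together with a Kolmogorov-Smirnov test of
#' p-value uniformity. The fixed-effect IVW z statistic is exactly standard
#' normal under this null, so the rejection rate estimates 0.05 up to
#' binomial noise.
#'
#' @param n_rep number of simulated null datasets (default 1000).
#' @param seed master seed.
#' @return list with `type1_error`, `ks_pval` and the vector of `pvals`.
#' @export
benchmark_null_calibration <- function(n_rep = 1000, seed = 1) {
  pvals <- vapply(seq_len(n_rep), function(i) {
    sp <- sim_pair(sim_config(seed = bench_seed(seed, 0L, i)))
    if (is.null(sp)) return(NA_real_)
    mr_ivw(sp$pair, model = "fixed")$pval
  }, numeric(1))
  pvals <- pvals[!is.na(pvals)]
  list(type1_error = mean(pvals < 0.05),
       ks_pval = stats::ks.test(pvals, "punif")$p.value,
       pvals = pvals)
}

# the strong-instrument benchmark regime: all three legs precise enough that
# replicate averages isolate estimator bias rather than sampling noise
strong_mediation_config <- function(seed, beta1_true = 0.3, beta2_true = 0.4,
                                    direct_true = 0.08) {
  sim_config(n_variants = 30, beta1_true = beta1_true,
             beta2_true = beta2_true, direct_true = direct_true,
             strong_fraction = 0.5, med_instrument_fraction = 0.3,
             n_med = 31684, case_fraction = 0.5,
             strong_z = c(20, 40), med_strong_z = c(20, 40), seed = seed)
}

#' Mediated-proportion recovery over simulation replicates
#'
#' Repeatedly simulates a triple with `beta1 = 0.3`, `beta2 = 0.4` and a
#' direct effect of 0.08 (true total 0.2, true mediated proportion 0.6) under
#' the strong-instrument benchmark regime, runs the full three-step mediation,
#' and aggregates the recovered proportions.
#'
#' @param n_rep replicates (default 200).
#' @param seed master seed.
#' @return list with `mean_proportion`, `sd`, `mc_se`, `true_proportion` and
#'   the replicate vector `proportions`.
#' @export
benchmark_mediation_recovery <- function(n_rep = 200, seed = 1) {
  props <- vapply(seq_len(n_rep), function(i) {
    cfg <- strong_mediation_config(bench_seed(seed, 200000L, i))
    sim <- simulate_triple(cfg)
    res <- tryCatch(
      run_mediation(sim$exposure, sim$mediator, sim$outcome, ld = sim$ld,
                    region = sim$region),
      error = function(e) NULL)
    if (is.null(res)) NA_real_ else res$proportion
  }, numeric(1))
  props <- props[!is.na(props)]
  list(mean_proportion = mean(props), sd = stats::sd(props),
       mc_se = stats::sd(props) / sqrt(length(props)),
       true_proportion = 0.6, proportions = props)
}

#' Egger-intercept recovery of planted directional pleiotropy
#'
#' Plants directional pleiotropy (mean `pleiotropy_mean`) on every instrument
#' of positively-oriented strong instruments and compares the replicate
#' average of the MR-Egger intercept with the planted mean, alongside the IVW
#' bias that the same pleiotropy induces.
#'
#' @param n_rep replicates (default 100).
#' @param seed master seed.
#' @param pleiotropy_mean planted mean direct effect (default 0.02).
#' @return list with `mean_intercept`, `mc_se`, `pleiotropy_mean`,
#'   `mean_ivw_bias` and the replicate vectors.
#' @export
benchmark_egger_pleiotropy <- function(n_rep = 100, seed = 1,
                                       pleiotropy_mean = 0.02) {
  true_total <- 0.1
  res <- vapply(seq_len(n_rep), function(i) {
    cfg <- sim_config(n_variants = 30, direct_true = true_total,
                      strong_fraction = 1, strong_sign = "positive",
                      strong_z = c(20, 40), case_fraction = 0.5,
                      pleiotropy = list(mode = "directional",
                                        mean = pleiotropy_mean, sd = 0.01,
                                        invalid_fraction = 1),
                      seed = bench_seed(seed, 300000L, i))
    sp <- sim_pair(cfg)
    if (is.null(sp)) return(c(NA_real_, NA_real_))
    c(mr_egger(sp$pair)$intercept,
      mr_ivw(sp$pair, model = "fixed")$beta - true_total)
  }, numeric(2))
  intercepts <- res[1, ][!is.na(res[1, ])]
  ivw_bias <- res[2, ][!is.na(res[2, ])]
  list(mean_intercept = mean(intercepts),
       mc_se = stats::sd(intercepts) / sqrt(length(intercepts)),
       pleiotropy_mean = pleiotropy_mean,
       mean_ivw_bias = mean(ivw_bias),
       intercepts = intercepts, ivw_bias = ivw_bias)
}

#' Weighted-median robustness at 40% invalid instruments
#'
#' Plants large directional pleiotropy on 40% of instruments (majority of
#' weight still valid) and compares the replicate means of the weighted
#' median and IVW estimates with the true total effect.
#'
#' @param n_rep replicates (default 100).
#' @param seed master seed.
#' @return list with `true_total`, `mean_wm`, `mean_ivw`, `wm_error`,
#'   `ivw_bias` and the replicate vectors.
#' @export
benchmark_median_robustness <- function(n_rep = 100, seed = 1) {
  true_total <- 0.1
  res <- vapply(seq_len(n_rep), function(i) {
    cfg <- sim_config(n_variants = 30, direct_true = true_total,
                      strong_fraction = 1, strong_sign = "positive",
                      strong_z = c(20, 40), case_fraction = 0.5,
                      pleiotropy = list(mode = "directional", mean = 0.12,
                                        sd = 0.02, invalid_fraction = 0.4),
                      seed = bench_seed(seed, 400000L, i))
    sp <- sim_pair(cfg)
    if (is.null(sp)) return(c(NA_real_, NA_real_))
    c(mr_weighted_median(sp$pair, n_boot = 10,
                         seed = bench_seed(seed, 450000L, i))$beta,
      mr_ivw(sp$pair, model = "fixed")$beta)
  }, numeric(2))
  wm <- res[1, ][!is.na(res[1, ])]
  ivw <- res[2, ][!is.na(res[2, ])]
  list(true_total = true_total, mean_wm = mean(wm), mean_ivw = mean(ivw),
       wm_error = mean(wm) - true_total, ivw_bias = mean(ivw) - true_total,
       wm = wm, ivw = ivw)
}

#' MR-PRESSO planted-outlier detection and clean-data specificity
#'
#' In each replicate of a 10-instrument design, one variant's outcome effect
#' is inflated by 10 outcome standard errors and MR-PRESSO is asked to flag
#' it; a matched clean replicate measures the per-variant false-flag rate.
#'
#' @param n_rep replicates (default 100).
#' @param seed master seed.
#' @param n_sim MR-PRESSO simulations per replicate (default 300).
#' @return list with `detection_rate`, `false_flag_rate` (per variant) and
#'   replicate counts.
#' @export
benchmark_presso_detection <- function(n_rep = 100, seed = 1, n_sim = 300) {
  detected <- logical(n_rep)
  false_flags <- integer(n_rep)
  n_variants <- 10L
  for (i in seq_len(n_rep)) {
    cfg <- sim_config(n_variants = n_variants, direct_true = 0.1,
                      strong_fraction = 1, strong_z = c(20, 40),
                      case_fraction = 0.5,
                      seed = bench_seed(seed, 500000L, i))
    sim <- simulate_triple(cfg)
    clean <- harmonize(sim$exposure, sim$outcome)
    res_clean <- mr_presso(clean, n_sim = n_sim,
                           seed = bench_seed(seed, 550000L, i))
    false_flags[i] <- length(res_clean$outliers)
    planted <- clean
    j <- 1L + (i %% n_variants)
    planted$rows$beta_out[j] <- planted$rows$beta_out[j] +
      10 * planted$rows$se_out[j]
    res <- mr_presso(planted, n_sim = n_sim,
                     seed = bench_seed(seed, 550000L, i))
    detected[i] <- planted$rows$variant_id[j] %in% res$outliers
  }
  list(detection_rate = mean(detected),
       false_flag_rate = sum(false_flags) / (n_rep * n_variants),
       detected = detected, false_flags = false_flags)
}
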
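# Synthetic GWAS summary-statistics generator with known causal truth:
# an exposure (cis-eQTL scale), a mediator downstream of the exposure
# (CSF-metabolite scale) and a binary outcome on the log-odds scale.

#' Shipped case/control presets for the binary-outcome regime
#'
#' Case fractions for the delirium outcome GWAS under its two published
#' case/control tallies (1,083/445,828 and 3,827/428,053).
#' @export
finngen_presets <- list(
  abstract = 1083 / (1083 + 445828),
  table1 = 3827 / (3827 + 428053)
)

#' Simulation configuration
#'
#' Defines the generative model: per-variant effects on a continuous exposure,
#' a continuous mediator causally downstream of the exposure, and a binary
#' outcome on the log-odds scale. Defaults mirror the emulated study regimes:
#' a blood cis-eQTL exposure (n = 31,684), a small CSF-metabolite mediator
#' GWAS (n = 291) and a large, heavily imbalanced binary outcome
#' (n = 431,880, case fraction 1,083/446,911).
#'
#' A `strong_fraction` of variants receive exposure effects scaled to a
#' z-score drawn from `strong_z`, guaranteeing genome-wide-significant
#' instruments; the rest get small effects (`instrument_effect_sd`).
#' `med_instrument_fraction` designates disjoint variants as mediator-specific
#' instruments (effects entering the outcome only through the mediator),
#' emulating the mediator GWAS supplying its own instruments. Pleiotropy
#' (`mode` `"none"`, `"balanced"` or `"directional"`) plants direct outcome
#' effects on an `invalid_fraction` of variants.
#'
#' @param n_variants number of variants (default 30).
#' @param maf_range range of minor allele frequencies (default 0.05--0.5).
#' @param n_exp,n_med,n_out sample sizes of the three GWAS.
#' @param case_fraction outcome case proportion in (0, 1).
#' @param beta1_true exposure-to-mediator effect.
#' @param beta2_true mediator-to-outcome effect (log-odds).
#' @param direct_true direct exposure-to-outcome effect (log-odds), not via
#'   the mediator.
#' @param instrument_effect_sd SD of the small (non-strong) exposure effects.
#' @param strong_fraction fraction of variants made strong exposure
#'   instruments.
#' @param strong_z z-score range targeted for strong exposure instruments.
#' @param strong_sign `"random"` (default) or `"positive"`: sign of the
#'   strong exposure effects. Directional pleiotropy is defined relative to
#'   the instruments' effect-allele orientation, so benchmarks planting a
#'   nonzero pleiotropy mean use `"positive"` to keep that orientation fixed.
#' @param med_instrument_fraction fraction made mediator-specific instruments.
#' @param med_strong_z z-score range for mediator-specific instruments.
#' @param pleiotropy list with `mode` ("none"/"balanced"/"directional"),
#'   `mean`, `sd`, `invalid_fraction`.
#' @param ld_rho AR(1) adjacent-variant LD correlation in [0, 1).
#' @param seed integer RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_variants = 30,
                       maf_range = c(0.05, 0.5),
                       n_exp = 31684, n_med = 291, n_out = 431880,
                       case_fraction = finngen_presets$abstract,
                       beta1_true = 0, beta2_true = 0, direct_true = 0,
                       instrument_effect_sd = 0.02,
                       strong_fraction = 0.5, strong_z = c(8, 16),
                       strong_sign = c("random", "positive"),
                       med_instrument_fraction = 0, med_strong_z = c(8, 16),
                       pleiotropy = list(mode = "none", mean = 0, sd = 0,
                                         invalid_fraction = 0),
                       ld_rho = 0, seed = 1) {
  maf_range <- as.numeric(unlist(maf_range))
  strong_z <- as.numeric(unlist(strong_z))
  med_strong_z <- as.numeric(unlist(med_strong_z))
  strong_sign <- match.arg(strong_sign)
  stopifnot(n_variants >= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            n_exp >= 4, n_med >= 4, n_out >= 4,
            case_fraction > 0, case_fraction < 1,
            instrument_effect_sd >= 0,
            strong_fraction >= 0, strong_fraction <= 1,
            med_instrument_fraction >= 0,
            strong_fraction + med_instrument_fraction <= 1,
            ld_rho >= 0, ld_rho < 1)
  pl <- utils::modifyList(list(mode = "none", mean = 0, sd = 0,
                               invalid_fraction = 0), pleiotropy)
  stopifnot(pl$mode %in% c("none", "balanced", "directional"),
            pl$sd >= 0, pl$invalid_fraction >= 0, pl$invalid_fraction <= 1)
  if (pl$mode == "balanced") pl$mean <- 0
  structure(list(n_variants = as.integer(n_variants), maf_range = maf_range,
                 n_exp = n_exp, n_med = n_med, n_out = n_out,
                 case_fraction = case_fraction,
                 beta1_true = beta1_true, beta2_true = beta2_true,
                 direct_true = direct_true,
                 instrument_effect_sd = instrument_effect_sd,
                 strong_fraction = strong_fraction, strong_z = strong_z,
                 strong_sign = strong_sign,
                 med_instrument_fraction = med_instrument_fraction,
                 med_strong_z = med_strong_z,
                 pleiotropy = pl, ld_rho = ld_rho,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an AR(1) LD correlation matrix
#'
#' Correlation `ld_rho^|i-j|` between the i-th and j-th variants; symmetric,
#' unit diagonal and positive definite for `ld_rho` in [0, 1).
#'
#' @param n_variants matrix dimension.
#' @param ld_rho adjacent-variant correlation in [0, 1).
#' @param variant_ids optional identifiers (defaults to `v1..vn`).
#' @return An `ld_matrix`.
#' @export
simulate_ld <- function(n_variants, ld_rho, variant_ids = NULL) {
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)", call. = FALSE)
  if (is.null(variant_ids)) variant_ids <- paste0("v", seq_len(n_variants))
  idx <- seq_len(n_variants)
  r <- ld_rho^abs(outer(idx, idx, "-"))
  ld_matrix(r, variant_ids)
}

# GWAS standard-error scale for a continuous (or, with case_fraction, binary
# logistic-score) trait
se_scale <- function(n, maf, case_fraction = NULL) {
  eff <- if (is.null(case_fraction)) n else n * case_fraction * (1 - case_fraction)
  1 / sqrt(eff * 2 * maf * (1 - maf))
}

NONPALINDROMIC_PAIRS <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                                 "G", "A", "C", "A", "G", "T", "C", "T"),
                               ncol = 2, byrow = TRUE)

#' Simulate an exposure/mediator/outcome summary-statistics triple
#'
#' Generates three GWAS summary-statistic sets sharing variants, positions and
#' allele codes, plus the LD matrix, a gene region covering the variants, and
#' the causal truth. Per-variant true effects follow the path-tracing rules of
#' the mediation diagram: exposure effects `gamma_j`; mediator effects
#' `gamma_j * beta1 + pi_med_j`; outcome effects
#' `gamma_j * (direct + beta1 * beta2) + pi_med_j * beta2 + pi_out_j`, where
#' `pi_med` holds mediator-specific instrument effects and `pi_out` the
#' planted pleiotropy of invalid variants. Observed effects are drawn
#' `Normal(true, se^2)` with GWAS standard errors
#' `se = 1/sqrt(n_eff * 2 maf (1-maf))` (`n_eff = n * cf * (1-cf)` for the
#' binary outcome); p-values from the two-sided z test. Fully reproducible
#' from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `exposure`, `mediator`, `outcome` (`sumstats`), `ld`
#'   (`ld_matrix`), `region` ([gene_region()]) and `truth` (list with
#'   `total_true`, `proportion_true`, per-variant true effects,
#'   `invalid_variant_ids`, `med_instrument_ids`, `strong_ids`).
#' @export
simulate_triple <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    k <- cfg$n_variants
    ids <- sprintf("rs%04d", seq_len(k))
    pos <- 1000000L + (seq_len(k) - 1L) * 5000L
    maf <- stats::runif(k, cfg$maf_range[1], cfg$maf_range[2])
    eaf <- ifelse(stats::runif(k) < 0.5, maf, 1 - maf)
    allele_idx <- sample.int(nrow(NONPALINDROMIC_PAIRS), k, replace = TRUE)
    ea <- NONPALINDROMIC_PAIRS[allele_idx, 1L]
    oa <- NONPALINDROMIC_PAIRS[allele_idx, 2L]

    se_exp <- se_scale(cfg$n_exp, maf)
    se_med <- se_scale(cfg$n_med, maf)
    se_out <- se_scale(cfg$n_out, maf, cfg$case_fraction)
    if (any(!is.finite(c(se_exp, se_med, se_out))) ||
        any(c(se_exp, se_med, se_out) <= 0)) {
      stop("configuration implies non-positive standard errors", call. = FALSE)
    }

    n_strong <- round(cfg$strong_fraction * k)
    n_medinst <- round(cfg$med_instrument_fraction * k)
    perm <- sample.int(k)
    strong_idx <- perm[seq_len(n_strong)]
    medinst_idx <- perm[n_strong + seq_len(n_medinst)]

    gamma <- stats::rnorm(k, 0, cfg$instrument_effect_sd)
    if (n_strong > 0) {
      signs <- if (cfg$strong_sign == "positive") rep(1, n_strong)
        else sample(c(-1, 1), n_strong, replace = TRUE)
      gamma[strong_idx] <- signs *
        stats::runif(n_strong, cfg$strong_z[1], cfg$strong_z[2]) *
        se_exp[strong_idx]
    }
    pi_med <- numeric(k)
    if (n_medinst > 0) {
      pi_med[medinst_idx] <- sample(c(-1, 1), n_medinst, replace = TRUE) *
        stats::runif(n_medinst, cfg$med_strong_z[1], cfg$med_strong_z[2]) *
        se_med[medinst_idx]
    }
    pl <- cfg$pleiotropy
    n_invalid <- round(pl$invalid_fraction * k)
    invalid_idx <- if (pl$mode == "none" || n_invalid == 0) integer(0)
      else sample.int(k, n_invalid)
    pi_out <- numeric(k)
    if (length(invalid_idx) > 0) {
      pi_out[invalid_idx] <- stats::rnorm(length(invalid_idx), pl$mean, pl$sd)
    }

    total_true <- cfg$direct_true + cfg$beta1_true * cfg$beta2_true
    true_exp <- gamma
    true_med <- gamma * cfg$beta1_true + pi_med
    true_out <- gamma * total_true + pi_med * cfg$beta2_true + pi_out

    obs <- function(true, se, n, trait_id, trait_type) {
      beta <- stats::rnorm(k, true, se)
      pval <- pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300)
      sumstats(data.frame(variant_id = ids, chrom = "1", pos = pos,
                          effect_allele = ea, other_allele = oa,
                          beta = beta, se = se, eaf = eaf, pval = pval,
                          n = n, stringsAsFactors = FALSE),
               trait_id = trait_id, trait_type = trait_type)
    }
    exposure <- obs(true_exp, se_exp, cfg$n_exp, "sim_exposure", "continuous")
    mediator <- obs(true_med, se_med, cfg$n_med, "sim_mediator", "continuous")
    outcome <- obs(true_out, se_out, cfg$n_out, "sim_outcome", "binary")

    list(exposure = exposure, mediator = mediator, outcome = outcome,
         ld = simulate_ld(k, cfg$ld_rho, ids),
         region = gene_region("sim_gene", "1", min(pos), max(pos)),
         truth = list(
           total_true = total_true,
           proportion_true = if (total_true != 0)
             cfg$beta1_true * cfg$beta2_true / total_true else NA_real_,
           beta1_true = cfg$beta1_true, beta2_true = cfg$beta2_true,
           direct_true = cfg$direct_true,
           per_variant = data.frame(variant_id = ids, exposure = true_exp,
                                    mediator = true_med, outcome = true_out,
                                    stringsAsFactors = FALSE),
           invalid_variant_ids = ids[invalid_idx],
           med_instrument_ids = ids[medinst_idx],
           strong_ids = ids[strong_idx],
           config = cfg))
  })
}

#' Compare a mediation result with the simulation truth
#'
#' @param truth the `truth` element of [simulate_triple()].
#' @param result a `mediation_result` from [run_mediation()].
#' @return data.frame with one row per parameter (`beta1`, `beta2`, `beta0`,
#'   `proportion`): true value, estimate, error (estimate - true).
#' @export
recovery_report <- function(truth, result) {
  true <- c(beta1 = truth$beta1_true, beta2 = truth$beta2_true,
            beta0 = truth$total_true, proportion = truth$proportion_true)
  est <- c(beta1 = result$beta1, beta2 = result$beta2,
           beta0 = result$beta0, proportion = result$proportion)
  data.frame(parameter = names(true), true = unname(true),
             estimated = unname(est), error = unname(est - true),
             stringsAsFactors = FALSE)
}

#' Write a simulated triple to disk
#'
#' Emits the three summary-statistic TSVs, the LD matrix TSV, the gene-region
#' TSV and a plain-text truth file into a directory.
#'
#' @param sim output of [simulate_triple()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_triple <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sumstats(sim$exposure, file.path(dir, "exposure.tsv"))
  write_sumstats(sim$mediator, file.path(dir, "mediator.tsv"))
  write_sumstats(sim$outcome, file.path(dir, "outcome.tsv"))
  write_ld_matrix(sim$ld, file.path(dir, "ld.tsv"))
  utils::write.table(as.data.frame(sim$region), file.path(dir, "region.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  lines <- c(paste0("total_true\t", truth$total_true),
             paste0("proportion_true\t", truth$proportion_true),
             paste0("beta1_true\t", truth$beta1_true),
             paste0("beta2_true\t", truth$beta2_true),
             paste0("direct_true\t", truth$direct_true))
  writeLines(lines, file.path(dir, "truth.tsv"))
  invisible(dir)
}
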
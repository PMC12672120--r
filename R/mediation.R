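# Two-step mediation: product-of-coefficients indirect effect, mediated
# proportion with delta-method CI, and FDR screening across exposures.

#' Indirect (mediated) effect by the product of coefficients
#'
#' `indirect = beta1 * beta2` with the Sobel / first-order delta-method
#' standard error `sqrt(beta2^2 se1^2 + beta1^2 se2^2)`; two-sided normal
#' test of `z = indirect / se`.
#'
#' @param beta1,se1 exposure-to-mediator effect and SE.
#' @param beta2,se2 mediator-to-outcome effect and SE.
#' @return list with `indirect`, `indirect_se`, `z`, `pval`.
#' @export
indirect_effect <- function(beta1, se1, beta2, se2) {
  if (!all(is.finite(c(beta1, se1, beta2, se2))) || se1 <= 0 || se2 <= 0) {
    stop("indirect_effect requires finite inputs with positive SEs",
         call. = FALSE)
  }
  indirect <- beta1 * beta2
  indirect_se <- sqrt(beta2^2 * se1^2 + beta1^2 * se2^2)
  z <- if (indirect_se > 0) indirect / indirect_se else 0
  list(indirect = indirect, indirect_se = indirect_se, z = z,
       pval = 2 * stats::pnorm(-abs(z)))
}

#' Proportion of the total effect that is mediated
#'
#' `proportion = indirect / beta0` with a symmetric 95% Wald interval. The
#' default standard error treats the total effect as fixed,
#' `se = |indirect_se / beta0|`; `method = "delta2"` adds the total effect's
#' own uncertainty through the two-term delta method
#' `se^2 = se_ind^2/beta0^2 + indirect^2 se0^2/beta0^4`.
#' A proportion outside `[0, 1]` (sign-discordant indirect vs total, or
#' indirect exceeding total) is returned verbatim with
#' `inconsistent_mediation = TRUE`, never clipped.
#'
#' @param indirect,indirect_se product-of-coefficients effect and SE.
#' @param beta0 total exposure-to-outcome effect (nonzero).
#' @param se0 total-effect SE (required for `method = "delta2"`).
#' @param method `"fixed_total"` (default) or `"delta2"`.
#' @return list with `proportion`, `lo95`, `hi95`, `se`,
#'   `inconsistent_mediation`.
#' @export
mediation_proportion <- function(indirect, indirect_se, beta0, se0 = NULL,
                                 method = c("fixed_total", "delta2")) {
  method <- match.arg(method)
  if (beta0 == 0) stop("mediated proportion undefined for beta0 = 0",
                       call. = FALSE)
  proportion <- indirect / beta0
  if (method == "fixed_total") {
    se <- abs(indirect_se / beta0)
  } else {
    if (is.null(se0)) stop("se0 required for the two-term delta method",
                           call. = FALSE)
    se <- sqrt(indirect_se^2 / beta0^2 + indirect^2 * se0^2 / beta0^4)
  }
  inconsistent <- proportion < 0 || proportion > 1
  if (proportion < 0) {
    warning("indirect and total effects have discordant signs; ",
            "mediated proportion is negative", call. = FALSE)
  }
  list(proportion = proportion,
       lo95 = proportion - Z95 * se,
       hi95 = proportion + Z95 * se,
       se = se,
       inconsistent_mediation = inconsistent)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment
#' (`q_(i) = min_{j >= i} p_(j) m / j`), returned in input order.
#'
#' @param pvals p-values in (0, 1].
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

# primary-method policy: IVW (multiplicative RE) for >= 2 instruments,
# Wald ratio for a single instrument
primary_estimate <- function(pair, ivw_model = "multiplicative_re") {
  mr_ivw(pair, model = ivw_model)
}

# one MR leg: select + clump instruments on the exposure side, harmonize to
# the outcome, estimate by the primary-method policy
mr_leg <- function(exposure_stats, outcome_stats, ld, region = NULL,
                   pval_max = 5e-8, maf_min = 0.01, f_min = 20,
                   cis_kb = 1000, clump_r2 = 0.1, clump_kb = 10000,
                   ivw_model = "multiplicative_re", step = "",
                   exclude_ids = NULL) {
  if (length(exclude_ids) > 0L) {
    keep <- !(exposure_stats$records$variant_id %in% exclude_ids)
    exposure_stats$records <- exposure_stats$records[keep, , drop = FALSE]
  }
  inst <- suppressWarnings(select_instruments(
    exposure_stats, region = region, pval_max = pval_max,
    maf_min = maf_min, f_min = f_min, cis_kb = cis_kb))
  if (nrow(inst$rows) == 0L) {
    stop("no valid instruments", if (nzchar(step)) paste0(" at ", step),
         " for ", exposure_stats$trait_id, call. = FALSE)
  }
  if (!is.null(ld)) inst <- ld_clump(inst, ld, r2_max = clump_r2,
                                     window_kb = clump_kb)
  exp_sub <- subset_to_instruments(exposure_stats, inst)
  pair <- harmonize(exp_sub, outcome_stats)
  v <- pair_vectors(pair)
  if (v$n == 0L) {
    stop("no instruments survive harmonization",
         if (nzchar(step)) paste0(" at ", step), call. = FALSE)
  }
  list(pair = pair, inst = inst, estimate = primary_estimate(pair, ivw_model))
}

#' Two-step summary-level mediation analysis
#'
#' Three MR legs: exposure to mediator (`beta1`), mediator to outcome
#' (`beta2`), and the total exposure-to-outcome effect (`beta0`), each
#' estimated by the primary-method policy (IVW with multiplicative random
#' effects for two or more instruments, Wald ratio for one). The indirect
#' effect is the product `beta1 * beta2` with a Sobel standard error, and the
#' mediated proportion is `indirect / beta0` with its Wald interval.
#'
#' @param exposure_stats,mediator_stats,outcome_stats `sumstats` objects.
#' @param ld optional `ld_matrix` covering the variants (for clumping).
#' @param region optional [gene_region()] for cis filtering of the exposure.
#' @param pval_max,maf_min,f_min,cis_kb,clump_r2,clump_kb instrument-selection
#'   thresholds for the exposure legs (steps 1 and 3).
#' @param med_pval_max significance threshold for mediator instruments
#'   (step 2); defaults to `pval_max`.
#' @param exclude_exposure_instruments drop the exposure's genome-wide-
#'   significant variants from the mediator leg (default `TRUE`). A variant
#'   acting on the mediator through the exposure is an invalid instrument for
#'   the mediator-to-outcome effect whenever a direct exposure-to-outcome
#'   path exists, so step 2 restricts to the mediator's own instruments.
#' @param ivw_model IVW model for all legs.
#' @param proportion_method passed to [mediation_proportion()].
#' @return A one-row data.frame of class `mediation_result` with the three
#'   path coefficients, the indirect effect, Sobel z and p, and the mediated
#'   proportion with 95% CI (both as fractions and flags).
#' @export
run_mediation <- function(exposure_stats, mediator_stats, outcome_stats,
                          ld = NULL, region = NULL,
                          pval_max = 5e-8, maf_min = 0.01, f_min = 20,
                          cis_kb = 1000, clump_r2 = 0.1, clump_kb = 10000,
                          med_pval_max = pval_max,
                          exclude_exposure_instruments = TRUE,
                          ivw_model = "multiplicative_re",
                          proportion_method = "fixed_total") {
  leg1 <- mr_leg(exposure_stats, mediator_stats, ld, region = region,
                 pval_max = pval_max, maf_min = maf_min, f_min = f_min,
                 cis_kb = cis_kb, clump_r2 = clump_r2, clump_kb = clump_kb,
                 ivw_model = ivw_model, step = "step1 (exposure->mediator)")
  exclude_ids <- if (exclude_exposure_instruments) {
    ex <- exposure_stats$records
    ex$variant_id[ex$pval < pval_max]
  } else NULL
  leg2 <- mr_leg(mediator_stats, outcome_stats, ld, region = NULL,
                 pval_max = med_pval_max, maf_min = maf_min, f_min = f_min,
                 ivw_model = ivw_model, step = "step2 (mediator->outcome)",
                 exclude_ids = exclude_ids)
  leg3 <- mr_leg(exposure_stats, outcome_stats, ld, region = region,
                 pval_max = pval_max, maf_min = maf_min, f_min = f_min,
                 cis_kb = cis_kb, clump_r2 = clump_r2, clump_kb = clump_kb,
                 ivw_model = ivw_model, step = "step3 (total effect)")
  b1 <- leg1$estimate; b2 <- leg2$estimate; b0 <- leg3$estimate
  ind <- indirect_effect(b1$beta, b1$se, b2$beta, b2$se)
  prop <- mediation_proportion(ind$indirect, ind$indirect_se, b0$beta,
                               se0 = b0$se, method = proportion_method)
  structure(data.frame(
    exposure_id = exposure_stats$trait_id,
    mediator_id = mediator_stats$trait_id,
    outcome_id = outcome_stats$trait_id,
    beta1 = b1$beta, se1 = b1$se, pval1 = b1$pval, nsnp1 = b1$nsnp,
    beta2 = b2$beta, se2 = b2$se, pval2 = b2$pval, nsnp2 = b2$nsnp,
    beta0 = b0$beta, se0 = b0$se, pval0 = b0$pval, nsnp0 = b0$nsnp,
    indirect = ind$indirect, indirect_se = ind$indirect_se,
    z = ind$z, pval = ind$pval,
    proportion = prop$proportion,
    prop_lo95 = prop$lo95, prop_hi95 = prop$hi95,
    inconsistent_mediation = prop$inconsistent_mediation,
    stringsAsFactors = FALSE
  ), class = c("mediation_result", "data.frame"))
}

#' Screen many exposures against one outcome
#'
#' Runs the primary-method MR (IVW / Wald ratio) for each exposure against the
#' outcome and adjusts the p-values across the screened family by
#' Benjamini-Hochberg. Exposures with no selectable instruments are emitted as
#' NA rows with a reason rather than dropped, so the FDR family size reflects
#' the scan as designed.
#'
#' @param exposures list of `sumstats` objects.
#' @param outcome outcome `sumstats`.
#' @param ld optional `ld_matrix` (clumping skipped when `NULL`).
#' @param regions optional list of [gene_region()] parallel to `exposures`.
#' @param pval_max,maf_min,f_min,cis_kb,clump_r2,clump_kb instrument
#'   thresholds.
#' @param ivw_model IVW model.
#' @return data.frame of class `screen_result`: per exposure the estimate,
#'   `fdr_q`, `significant_raw` (p < 0.05) and `significant_fdr` (q < 0.05)
#'   flags, and a `reason` column for failed rows.
#' @export
mr_screen <- function(exposures, outcome, ld = NULL, regions = NULL,
                      pval_max = 5e-8, maf_min = 0.01, f_min = 20,
                      cis_kb = 1000, clump_r2 = 0.1, clump_kb = 10000,
                      ivw_model = "multiplicative_re") {
  stopifnot(length(exposures) >= 1)
  rows <- lapply(seq_along(exposures), function(i) {
    ex <- exposures[[i]]
    region <- if (is.null(regions)) NULL else regions[[i]]
    res <- tryCatch(
      mr_leg(ex, outcome, ld, region = region, pval_max = pval_max,
             maf_min = maf_min, f_min = f_min, cis_kb = cis_kb,
             clump_r2 = clump_r2, clump_kb = clump_kb, ivw_model = ivw_model),
      error = function(e) e)
    if (inherits(res, "error")) {
      reason <- if (grepl("no valid instruments", conditionMessage(res)))
        "no_instruments" else conditionMessage(res)
      data.frame(exposure_id = ex$trait_id, outcome_id = outcome$trait_id,
                 method = NA_character_, nsnp = NA_integer_, beta = NA_real_,
                 se = NA_real_, pval = NA_real_, or = NA_real_,
                 or_lo95 = NA_real_, or_hi95 = NA_real_,
                 reason = reason, stringsAsFactors = FALSE)
    } else {
      e <- res$estimate
      data.frame(exposure_id = ex$trait_id, outcome_id = outcome$trait_id,
                 method = e$method, nsnp = e$nsnp, beta = e$beta, se = e$se,
                 pval = e$pval, or = e$or, or_lo95 = e$or_lo95,
                 or_hi95 = e$or_hi95, reason = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$fdr_q <- NA_real_
  ok <- !is.na(out$pval)
  if (any(ok)) out$fdr_q[ok] <- bh_fdr(out$pval[ok])
  out$significant_raw <- !is.na(out$pval) & out$pval < 0.05
  out$significant_fdr <- !is.na(out$fdr_q) & out$fdr_q < 0.05
  class(out) <- c("screen_result", "data.frame")
  out
}
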
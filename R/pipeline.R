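# Config-driven orchestration of the full workflow: exposure scans,
# sensitivity reports and mediation for qualifying triples.

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ", ...)
  writeLines(msg, con)
}

cfg_get <- function(cfg, path, default = NULL) {
  for (key in path) {
    if (is.null(cfg) || is.null(cfg[[key]])) return(default)
    cfg <- cfg[[key]]
  }
  cfg
}

#' Read and validate a run configuration
#'
#' YAML with exactly one of an `inputs` block (paths to summary-statistic,
#' LD and region files) or a `simulate` block (a [sim_config()] plus an
#' optional `exposures` list of per-exposure overrides), together with
#' optional `instruments`, `methods` and `mediation` blocks and a mandatory
#' `seed`. A single seed fans out deterministically to every stochastic
#' component (per-exposure simulations, bootstrap and MR-PRESSO seeds).
#'
#' @param path YAML file path.
#' @return The validated config list, class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a config list (as parsed from YAML).
#' @export
validate_run_config <- function(cfg) {
  has_inputs <- !is.null(cfg$inputs)
  has_sim <- !is.null(cfg$simulate)
  if (has_inputs == has_sim) {
    stop("config must contain exactly one of 'inputs' or 'simulate'",
         call. = FALSE)
  }
  if (is.null(cfg$seed)) stop("config must set a seed", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

# instrument thresholds with spec defaults
inst_cfg <- function(cfg) {
  list(pval_max = cfg_get(cfg, c("instruments", "pval_max"), 5e-8),
       maf_min = cfg_get(cfg, c("instruments", "maf_min"), 0.01),
       f_min = cfg_get(cfg, c("instruments", "f_min"), 20),
       cis_kb = cfg_get(cfg, c("instruments", "cis_kb"), 1000),
       clump_r2 = cfg_get(cfg, c("instruments", "clump_r2"), 0.1),
       clump_kb = cfg_get(cfg, c("instruments", "clump_kb"), 10000))
}

method_cfg <- function(cfg) {
  list(ivw_model = cfg_get(cfg, c("methods", "ivw_model"), "multiplicative_re"),
       n_boot = cfg_get(cfg, c("methods", "n_boot"), 5000),
       presso_n_sim = cfg_get(cfg, c("methods", "presso_n_sim"), 1000))
}

# materialize datasets: one triple per configured exposure
load_datasets <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    base <- cfg$simulate
    overrides <- base$exposures
    base$exposures <- NULL
    if (is.null(overrides)) overrides <- list(list(id = "exposure1"))
    lapply(seq_along(overrides), function(i) {
      ov <- overrides[[i]]
      id <- if (is.null(ov$id)) paste0("exposure", i) else ov$id
      ov$id <- NULL
      args <- utils::modifyList(base, ov)
      args$seed <- cfg$seed + i
      sc <- do.call(sim_config, args)
      sim <- simulate_triple(sc)
      sim$exposure$trait_id <- id
      list(id = id, exposure = sim$exposure, mediator = sim$mediator,
           outcome = sim$outcome, ld = sim$ld, region = sim$region,
           truth = sim$truth)
    })
  } else {
    inp <- cfg$inputs
    outcome <- read_sumstats(inp$outcome, trait_id = "outcome",
                             trait_type = "binary")
    ld <- if (is.null(inp$ld)) NULL else read_ld_matrix(inp$ld)
    regions <- if (is.null(inp$regions)) NULL else read_gene_regions(inp$regions)
    lapply(inp$exposures, function(ex) {
      id <- if (is.null(ex$id)) basename(ex$path) else ex$id
      exposure <- read_sumstats(ex$path, trait_id = id,
                                trait_type = "continuous")
      mediator <- if (is.null(ex$mediator)) NULL
        else read_sumstats(ex$mediator, trait_id = paste0(id, "_mediator"),
                           trait_type = "continuous")
      region <- NULL
      if (!is.null(regions) && !is.null(ex$gene_id)) {
        row <- regions[regions$gene_id == ex$gene_id, ]
        if (nrow(row) == 1) region <- gene_region(row$gene_id, row$chrom,
                                                  row$start, row$end)
      }
      list(id = id, exposure = exposure, mediator = mediator,
           outcome = outcome, ld = ld, region = region, truth = NULL)
    })
  }
}

#' Run the exposure-to-outcome scan
#'
#' For every configured exposure: select and clump instruments, harmonize to
#' the outcome, run all applicable MR estimators and the sensitivity suite,
#' and write `scan.tsv` (one row per method per pair), `sensitivity.tsv` and
#' a run log recording seed, thresholds and package version.
#'
#' @param cfg a `run_config` (or path to one).
#' @param out_dir output directory; defaults to `cfg$output_dir` or `"."`.
#' @return Invisibly, a list with the scan and sensitivity data.frames and
#'   output paths.
#' @export
run_scan <- function(cfg, out_dir = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  cfg <- validate_run_config(unclass(cfg))
  ic <- inst_cfg(cfg)
  mc <- method_cfg(cfg)
  if (is.null(out_dir)) out_dir <- cfg_get(cfg, "output_dir", ".")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(out_dir, "scan.log"), open = "wt")
  on.exit(close(logf))
  log_line(logf, "mrmediate scan start, package version ",
           as.character(utils::packageVersion("mrmediate")))
  log_line(logf, "seed=", cfg$seed,
           " pval_max=", ic$pval_max, " maf_min=", ic$maf_min,
           " f_min=", ic$f_min, " cis_kb=", ic$cis_kb,
           " clump_r2=", ic$clump_r2, " clump_kb=", ic$clump_kb,
           " ivw_model=", mc$ivw_model)

  datasets <- load_datasets(cfg)
  scan_rows <- list()
  sens_rows <- list()
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    leg <- tryCatch(
      mr_leg(d$exposure, d$outcome, d$ld, region = d$region,
             pval_max = ic$pval_max, maf_min = ic$maf_min, f_min = ic$f_min,
             cis_kb = ic$cis_kb, clump_r2 = ic$clump_r2,
             clump_kb = ic$clump_kb, ivw_model = mc$ivw_model),
      error = function(e) e)
    if (inherits(leg, "error")) {
      log_line(logf, "exposure ", d$id, ": ", conditionMessage(leg))
      next
    }
    ests <- mr_all(leg$pair, ivw_model = mc$ivw_model, n_boot = mc$n_boot,
                   seed = cfg$seed + 1000L + i)
    ests <- cbind(exposure_id = d$id, outcome_id = d$outcome$trait_id, ests)
    scan_rows[[length(scan_rows) + 1L]] <- ests
    sr <- sensitivity_report(leg$pair, leg$inst, d$outcome,
                             n_sim = mc$presso_n_sim,
                             seed = cfg$seed + 2000L + i)
    sens_rows[[length(sens_rows) + 1L]] <- data.frame(
      exposure_id = d$id, outcome_id = d$outcome$trait_id,
      nsnp = leg$estimate$nsnp,
      q_stat = sr$q_stat, q_df = sr$q_df, q_pval = sr$q_pval,
      egger_intercept = sr$egger_intercept,
      egger_intercept_pval = sr$egger_intercept_pval,
      presso_global_pval = sr$presso_global_pval,
      presso_n_outliers = length(sr$presso_outliers),
      steiger_correct_direction = sr$steiger_correct_direction,
      steiger_pval = sr$steiger_pval,
      stringsAsFactors = FALSE)
    log_line(logf, "exposure ", d$id, ": ", leg$estimate$nsnp,
             " instruments, IVW beta=", signif(leg$estimate$beta, 4),
             " p=", signif(leg$estimate$pval, 3))
  }
  scan <- if (length(scan_rows)) do.call(rbind, scan_rows) else
    data.frame(exposure_id = character(0))
  sens <- if (length(sens_rows)) do.call(rbind, sens_rows) else
    data.frame(exposure_id = character(0))
  scan_path <- file.path(out_dir, "scan.tsv")
  sens_path <- file.path(out_dir, "sensitivity.tsv")
  utils::write.table(scan, scan_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sens, sens_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  log_line(logf, "scan complete: ", length(scan_rows), " exposure(s) written")
  invisible(list(scan = scan, sensitivity = sens,
                 paths = c(scan = scan_path, sensitivity = sens_path)))
}

#' Run the mediation workflow
#'
#' For every configured exposure with a mediator, applies the significance
#' gates (raw p below `mediation$gate_pval`, default 0.05, on both the
#' exposure-to-outcome and mediator-to-outcome scans) and runs the three-step
#' mediation for qualifying pairs, writing `mediation.tsv`. The log records
#' the three step labels and the mediated proportion with its 95% CI in
#' percent (2 decimals). An empty result is written (exit normally) when no
#' pair qualifies.
#'
#' @param cfg a `run_config` (or path to one).
#' @param out_dir output directory; defaults to `cfg$output_dir` or `"."`.
#' @return Invisibly, a list with the mediation data.frame and output path.
#' @export
run_mediate <- function(cfg, out_dir = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  cfg <- validate_run_config(unclass(cfg))
  ic <- inst_cfg(cfg)
  mc <- method_cfg(cfg)
  gate_pval <- cfg_get(cfg, c("mediation", "gate_pval"), 0.05)
  med_pval_max <- cfg_get(cfg, c("mediation", "med_pval_max"), ic$pval_max)
  if (is.null(out_dir)) out_dir <- cfg_get(cfg, "output_dir", ".")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(out_dir, "mediate.log"), open = "wt")
  on.exit(close(logf))
  log_line(logf, "mrmediate mediate start, seed=", cfg$seed,
           " gate_pval=", gate_pval)

  datasets <- load_datasets(cfg)
  med_cols <- c("exposure_id", "mediator_id", "outcome_id",
                "beta1", "se1", "beta2", "se2", "beta0", "se0",
                "indirect", "indirect_se", "z", "pval",
                "proportion_pct", "prop_lo95_pct", "prop_hi95_pct", "flags")
  rows <- list()
  for (d in datasets) {
    if (is.null(d$mediator)) next
    gate_exp <- tryCatch(
      mr_leg(d$exposure, d$outcome, d$ld, region = d$region,
             pval_max = ic$pval_max, maf_min = ic$maf_min, f_min = ic$f_min,
             cis_kb = ic$cis_kb, clump_r2 = ic$clump_r2,
             clump_kb = ic$clump_kb, ivw_model = mc$ivw_model)$estimate$pval,
      error = function(e) NA_real_)
    exclude_ids <- d$exposure$records$variant_id[
      d$exposure$records$pval < ic$pval_max]
    gate_med <- tryCatch(
      mr_leg(d$mediator, d$outcome, d$ld, pval_max = med_pval_max,
             maf_min = ic$maf_min, f_min = ic$f_min,
             clump_r2 = ic$clump_r2, clump_kb = ic$clump_kb,
             ivw_model = mc$ivw_model,
             exclude_ids = exclude_ids)$estimate$pval,
      error = function(e) NA_real_)
    if (is.na(gate_exp) || gate_exp >= gate_pval ||
        is.na(gate_med) || gate_med >= gate_pval) {
      log_line(logf, "pair ", d$id, "/", d$mediator$trait_id,
               " does not pass the p<", gate_pval, " gates (p_exp=",
               signif(gate_exp, 3), ", p_med=", signif(gate_med, 3), ")")
      next
    }
    res <- tryCatch(
      run_mediation(d$exposure, d$mediator, d$outcome, ld = d$ld,
                    region = d$region, pval_max = ic$pval_max,
                    maf_min = ic$maf_min, f_min = ic$f_min,
                    cis_kb = ic$cis_kb, clump_r2 = ic$clump_r2,
                    clump_kb = ic$clump_kb, med_pval_max = med_pval_max,
                    ivw_model = mc$ivw_model),
      error = function(e) e)
    if (inherits(res, "error")) {
      log_line(logf, "mediation failed for ", d$id, ": ",
               conditionMessage(res))
      next
    }
    log_line(logf, "step1 (exposure->mediator) ", d$id, ": beta1=",
             signif(res$beta1, 4), " (", res$nsnp1, " instruments)")
    log_line(logf, "step2 (mediator->outcome) ", res$mediator_id, ": beta2=",
             signif(res$beta2, 4), " (", res$nsnp2, " instruments)")
    log_line(logf, "step3 (total effect) ", d$id, ": beta0=",
             signif(res$beta0, 4), " (", res$nsnp0, " instruments)")
    log_line(logf, "mediated proportion ",
             sprintf("%.2f%% (95%% CI %.2f%% to %.2f%%), Z = %.3f",
                     100 * res$proportion, 100 * res$prop_lo95,
                     100 * res$prop_hi95, res$z))
    rows[[length(rows) + 1L]] <- data.frame(
      exposure_id = res$exposure_id, mediator_id = res$mediator_id,
      outcome_id = res$outcome_id,
      beta1 = res$beta1, se1 = res$se1, beta2 = res$beta2, se2 = res$se2,
      beta0 = res$beta0, se0 = res$se0,
      indirect = res$indirect, indirect_se = res$indirect_se,
      z = res$z, pval = res$pval,
      proportion_pct = 100 * res$proportion,
      prop_lo95_pct = 100 * res$prop_lo95,
      prop_hi95_pct = 100 * res$prop_hi95,
      flags = if (res$inconsistent_mediation) "inconsistent_mediation" else "",
      stringsAsFactors = FALSE)
  }
  med <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(med_cols))),
                    med_cols)
  med_path <- file.path(out_dir, "mediation.tsv")
  utils::write.table(med, med_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (length(rows) == 0L) log_line(logf, "no qualifying pairs; empty output")
  log_line(logf, "mediation complete: ", length(rows), " row(s)")
  invisible(list(mediation = med, paths = c(mediation = med_path)))
}
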
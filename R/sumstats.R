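# GWAS summary-statistic containers, file I/O, allele harmonization and
# genomic-control adjustment.

SUMSTAT_COLS <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                  "beta", "se", "eaf", "pval", "n")

#' Construct a summary-statistic set
#'
#' Bundles per-variant GWAS association records for one trait into a validated
#' container. Each record carries identifier, position, allele pair, per-allele
#' effect size (log odds ratio for binary traits), standard error,
#' effect-allele frequency, p-value and effective sample size.
#'
#' Rows violating the record invariants (`se > 0`, distinct alleles, `pos >= 1`,
#' `eaf` in (0,1) when present, `pval` in (0,1]) are dropped with a warning
#' counting them; duplicated `variant_id`s are an error.
#'
#' @param records data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `eaf`, `pval`, `n`.
#'   `eaf` may be `NA`.
#' @param trait_id character scalar naming the trait.
#' @param trait_type `"continuous"` or `"binary"`; for binary traits `beta` is
#'   interpreted on the log-odds scale.
#' @return An object of class `sumstats`: a list with elements `trait_id`,
#'   `trait_type` and `records`.
#' @export
sumstats <- function(records, trait_id, trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.character(trait_id), length(trait_id) == 1L)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SUMSTAT_COLS, names(records))
  if (length(missing_cols) > 0L) {
    stop("summary-statistic table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- records[SUMSTAT_COLS]
  for (col in c("pos", "beta", "se", "eaf", "pval", "n")) {
    if (!is.numeric(records[[col]])) {
      suppressWarnings(num <- as.numeric(records[[col]]))
      bad <- which(!is.na(records[[col]]) & records[[col]] != "" &
                     records[[col]] != "NA" & is.na(num))
      if (length(bad) > 0L) {
        stop("non-numeric ", col, " for variant(s): ",
             paste(records$variant_id[utils::head(bad, 5L)], collapse = ", "),
             call. = FALSE)
      }
      records[[col]] <- num
    }
  }
  for (col in c("variant_id", "chrom", "effect_allele", "other_allele")) {
    records[[col]] <- as.character(records[[col]])
  }
  ok <- is.finite(records$beta) & is.finite(records$se) & records$se > 0 &
    records$effect_allele != records$other_allele &
    is.finite(records$pos) & records$pos >= 1 &
    (is.na(records$eaf) | (records$eaf > 0 & records$eaf < 1)) &
    is.finite(records$pval) & records$pval > 0 & records$pval <= 1 &
    is.finite(records$n) & records$n > 0
  if (any(!ok)) {
    warning(sum(!ok), " of ", nrow(records),
            " record(s) rejected for violating summary-statistic invariants",
            call. = FALSE)
    records <- records[ok, , drop = FALSE]
  }
  if (anyDuplicated(records$variant_id)) {
    stop("duplicate variant_id in summary statistics for trait ", trait_id,
         call. = FALSE)
  }
  rownames(records) <- NULL
  structure(list(trait_id = trait_id, trait_type = trait_type,
                 records = records),
            class = "sumstats")
}

#' @export
print.sumstats <- function(x, ...) {
  cat("GWAS summary statistics: ", x$trait_id, " (", x$trait_type, "), ",
      nrow(x$records), " variants\n", sep = "")
  invisible(x)
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' Expects a header naming the ten standard fields (see [sumstats()]);
#' non-standard column names can be remapped via `col_map`. Missing values are
#' encoded as `NA`.
#'
#' @param path file path of a tab-separated table.
#' @param trait_id,trait_type passed to [sumstats()].
#' @param col_map optional named character vector mapping standard field names
#'   to the column names used in the file, e.g. `c(variant_id = "SNP")`.
#' @return A `sumstats` object.
#' @export
read_sumstats <- function(path, trait_id, trait_type = c("continuous", "binary"),
                          col_map = NULL) {
  trait_type <- match.arg(trait_type)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA",
                          colClasses = NA, check.names = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (!col_map[[std]] %in% names(df)) {
        stop("column '", col_map[[std]], "' (mapped to ", std,
             ") not found in ", path, call. = FALSE)
      }
      names(df)[names(df) == col_map[[std]]] <- std
    }
  }
  missing_cols <- setdiff(SUMSTAT_COLS, names(df))
  if (length(missing_cols) > 0L) {
    stop("file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sumstats(df, trait_id = trait_id, trait_type = trait_type)
}

#' Write GWAS summary statistics to a tab-separated file
#'
#' Numeric fields are serialized at 15 significant digits so that
#' `read_sumstats(write_sumstats(s, path))` reproduces `s` exactly; missing
#' values are written as `NA`.
#'
#' @param s a `sumstats` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(s, path) {
  stopifnot(inherits(s, "sumstats"))
  df <- s$records
  for (col in c("beta", "se", "eaf", "pval")) {
    df[[col]] <- ifelse(is.na(df[[col]]), NA_character_,
                        formatC(df[[col]], digits = 15, format = "g"))
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write summary statistics to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(a1, a2) COMPLEMENT[a1] == a2

#' Harmonize exposure and outcome summary statistics to shared effect alleles
#'
#' Aligns the outcome effects to the exposure's effect-allele coding for every
#' variant present in both sets. Variants with identical allele pairs are kept
#' as is; swapped pairs have the outcome beta sign-flipped and `eaf` reflected;
#' strand-complement codings are complemented first. Palindromic (A/T, G/C)
#' variants cannot be resolved from alleles alone and are aligned from allele
#' frequency: if both frequencies fall outside the ambiguous window around 0.5
#' they are kept (same side) or flipped (opposite sides), otherwise dropped.
#'
#' @param exposure,outcome `sumstats` objects.
#' @param palindromic_eaf_window half-width of the ambiguous frequency zone
#'   around 0.5 (default 0.08, i.e. 0.42--0.58).
#' @return An object of class `harmonized_pair`: list with `exposure_id`,
#'   `outcome_id` and a per-variant data.frame `rows` whose `action` column is
#'   one of `kept`, `flipped`, `dropped_palindromic`, `dropped_missing`.
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_window = 0.08) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  ex <- exposure$records
  ou <- outcome$records
  shared <- intersect(ex$variant_id, ou$variant_id)
  if (length(shared) == 0L) {
    stop("no shared variants between ", exposure$trait_id, " and ",
         outcome$trait_id, call. = FALSE)
  }
  ex <- ex[match(shared, ex$variant_id), ]
  ou <- ou[match(shared, ou$variant_id), ]

  n <- length(shared)
  action <- rep(NA_character_, n)
  beta_out <- ou$beta
  eaf_out <- ou$eaf

  ea_e <- ex$effect_allele; oa_e <- ex$other_allele
  ea_o <- ou$effect_allele; oa_o <- ou$other_allele
  pal <- is_palindromic(ea_e, oa_e)

  for (i in seq_len(n)) {
    if (pal[i]) {
      # alleles of a palindromic variant match under every strand hypothesis;
      # allele frequency is the only alignment signal
      same_pair <- (ea_o[i] == ea_e[i] && oa_o[i] == oa_e[i]) ||
        (ea_o[i] == COMPLEMENT[ea_e[i]] && oa_o[i] == COMPLEMENT[oa_e[i]])
      swapped_pair <- (ea_o[i] == oa_e[i] && oa_o[i] == ea_e[i]) ||
        (ea_o[i] == COMPLEMENT[oa_e[i]] && oa_o[i] == COMPLEMENT[ea_e[i]])
      if (!same_pair && !swapped_pair) { action[i] <- "dropped_missing"; next }
      fe <- ex$eaf[i]; fo <- ou$eaf[i]
      if (is.na(fe) || is.na(fo) ||
          abs(fe - 0.5) <= palindromic_eaf_window ||
          abs(fo - 0.5) <= palindromic_eaf_window) {
        action[i] <- "dropped_palindromic"
      } else if ((fe < 0.5) == (fo < 0.5)) {
        action[i] <- "kept"
      } else {
        action[i] <- "flipped"
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
      }
    } else {
      if (ea_o[i] == ea_e[i] && oa_o[i] == oa_e[i]) {
        action[i] <- "kept"
      } else if (ea_o[i] == oa_e[i] && oa_o[i] == ea_e[i]) {
        action[i] <- "flipped"
        beta_out[i] <- -beta_out[i]
        if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
      } else if (ea_o[i] == COMPLEMENT[ea_e[i]] && oa_o[i] == COMPLEMENT[oa_e[i]]) {
        action[i] <- "kept"
      } else if (ea_o[i] == COMPLEMENT[oa_e[i]] && oa_o[i] == COMPLEMENT[ea_e[i]]) {
        action[i] <- "flipped"
        beta_out[i] <- -beta_out[i]
        if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
      } else {
        action[i] <- "dropped_missing"  # incompatible allele pair
      }
    }
  }

  dropped <- action %in% c("dropped_palindromic", "dropped_missing")
  rows <- data.frame(
    variant_id = shared,
    beta_exp = ex$beta, se_exp = ex$se, eaf_exp = ex$eaf,
    pval_exp = ex$pval, n_exp = ex$n,
    beta_out = ifelse(dropped, NA_real_, beta_out),
    se_out = ifelse(dropped, NA_real_, ou$se),
    eaf_out = ifelse(dropped, NA_real_, eaf_out),
    n_out = ou$n,
    action = action,
    stringsAsFactors = FALSE
  )
  rows$beta_exp[dropped] <- NA_real_
  rows$se_exp[dropped] <- NA_real_
  structure(list(exposure_id = exposure$trait_id,
                 outcome_id = outcome$trait_id,
                 rows = rows),
            class = "harmonized_pair")
}

#' @export
print.harmonized_pair <- function(x, ...) {
  tab <- table(x$rows$action)
  cat("Harmonized pair ", x$exposure_id, " -> ", x$outcome_id, ": ",
      nrow(x$rows), " shared variants (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# rows usable for estimation (kept or flipped)
kept_rows <- function(pair) {
  stopifnot(inherits(pair, "harmonized_pair"))
  pair$rows[pair$rows$action %in% c("kept", "flipped"), , drop = FALSE]
}

CHISQ1_MEDIAN <- stats::qchisq(0.5, df = 1)  # 0.4549364

#' Genomic-control adjustment of a summary-statistic set
#'
#' Computes the genomic inflation factor
#' `lambda_gc = median((beta/se)^2) / 0.4549364` (the median of the chi-square
#' distribution with 1 df). When `lambda_gc > 1`, every standard error is
#' multiplied by `sqrt(lambda_gc)` and p-values are recomputed from the
#' adjusted two-sided z test. Genomic control is an inflation correction, so
#' `lambda_gc <= 1` leaves the set unchanged (no deflation).
#'
#' @param s a `sumstats` object with at least one record.
#' @return A list with elements `sumstats` (the adjusted set) and `lambda_gc`.
#' @export
genomic_control_adjust <- function(s) {
  stopifnot(inherits(s, "sumstats"))
  if (nrow(s$records) == 0L) stop("empty summary-statistic set", call. = FALSE)
  z2 <- (s$records$beta / s$records$se)^2
  lambda_gc <- stats::median(z2) / CHISQ1_MEDIAN
  if (lambda_gc > 1) {
    s$records$se <- s$records$se * sqrt(lambda_gc)
    z <- s$records$beta / s$records$se
    s$records$pval <- 2 * stats::pnorm(-abs(z))
  }
  list(sumstats = s, lambda_gc = lambda_gc)
}
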
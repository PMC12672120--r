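# Instrument selection: significance / frequency / cis-window / strength
# filters and greedy LD clumping.

#' Variance in the exposure explained by one variant
#'
#' `R^2 = 2 (1 - MAF) MAF beta^2` with `MAF = min(eaf, 1 - eaf)`; the additive
#' variance of a per-allele effect `beta` on a unit-variance trait.
#'
#' @param eaf effect-allele frequency in (0, 1).
#' @param beta per-allele effect size on the exposure.
#' @return Variance explained, in `[0, beta^2 / 2]`. Vectorized.
#' @export
variant_r2 <- function(eaf, beta) {
  if (any(!is.finite(eaf)) || any(eaf <= 0) || any(eaf >= 1)) {
    stop("eaf must lie strictly between 0 and 1", call. = FALSE)
  }
  maf <- pmin(eaf, 1 - eaf)
  2 * (1 - maf) * maf * beta^2
}

#' Instrument-strength F statistic
#'
#' `F = R^2 (N - 2) / (1 - R^2)`, the one-instrument F statistic from the
#' variance explained and the effective sample size. F >= 20 is the
#' conventional bar against weak-instrument bias here.
#'
#' @param r2 variance explained, in `[0, 1)`.
#' @param n effective sample size (>= 3).
#' @return F statistic (>= 0). Vectorized.
#' @export
f_statistic <- function(r2, n) {
  if (any(!is.finite(r2)) || any(r2 < 0) || any(r2 >= 1)) {
    stop("r2 must lie in [0, 1)", call. = FALSE)
  }
  if (any(n < 3)) stop("n must be at least 3", call. = FALSE)
  r2 * (n - 2) / (1 - r2)
}

#' Define a gene region
#'
#' 1-based inclusive coordinates; the anchor for cis-window instrument
#' filtering.
#'
#' @param gene_id,chrom character scalars.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @return A one-row data.frame of class `gene_region`.
#' @export
gene_region <- function(gene_id, chrom, start, end) {
  stopifnot(start <= end, start >= 1)
  structure(data.frame(gene_id = as.character(gene_id),
                       chrom = as.character(chrom),
                       start = as.integer(start), end = as.integer(end),
                       stringsAsFactors = FALSE),
            class = c("gene_region", "data.frame"))
}

#' Read gene regions from a 4-column tab-separated file
#'
#' Columns `gene_id`, `chrom`, `start`, `end`; coordinates are 1-based
#' inclusive (unlike 0-based half-open BED).
#'
#' @param path file path.
#' @return data.frame of regions.
#' @export
read_gene_regions <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("region file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df[need]
}

#' Select genetic instruments for an exposure
#'
#' Retains variants passing all of: association p-value below `pval_max`,
#' minor allele frequency above `maf_min`, single-variant F statistic at least
#' `f_min`, and (when a gene region is supplied) position within
#' `cis_kb` kilobases of the gene on the same chromosome (window inclusive).
#' Retained rows are annotated with `r2_variant` and `f_stat`.
#'
#' @param s a `sumstats` object for the exposure.
#' @param region optional [gene_region()] for cis filtering.
#' @param pval_max genome-wide significance threshold (default 5e-8).
#' @param maf_min minor-allele-frequency floor (default 0.01, exclusive).
#' @param f_min minimum F statistic (default 20).
#' @param cis_kb half-width of the cis window in kb (default 1000).
#' @return An `instrument_set`: list with `exposure_id` and data.frame `rows`.
#'   Empty (with a warning) when no variant passes.
#' @export
select_instruments <- function(s, region = NULL, pval_max = 5e-8,
                               maf_min = 0.01, f_min = 20, cis_kb = 1000) {
  stopifnot(inherits(s, "sumstats"))
  rows <- s$records
  maf <- pmin(rows$eaf, 1 - rows$eaf)
  r2 <- ifelse(is.na(rows$eaf), NA_real_, 2 * (1 - maf) * maf * rows$beta^2)
  fstat <- ifelse(is.na(r2) | r2 >= 1, NA_real_, r2 * (rows$n - 2) / (1 - r2))
  keep <- rows$pval < pval_max &
    !is.na(maf) & maf > maf_min &
    !is.na(fstat) & fstat >= f_min
  if (!is.null(region)) {
    lo <- region$start - cis_kb * 1000
    hi <- region$end + cis_kb * 1000
    keep <- keep & rows$chrom == region$chrom & rows$pos >= lo & rows$pos <= hi
  }
  keep[is.na(keep)] <- FALSE
  out <- rows[keep, , drop = FALSE]
  out$r2_variant <- r2[keep]
  out$f_stat <- fstat[keep]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    warning("no instruments pass the filters for ", s$trait_id, call. = FALSE)
  }
  structure(list(exposure_id = s$trait_id, rows = out),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("Instrument set for ", x$exposure_id, ": ", nrow(x$rows),
      " variant(s)\n", sep = "")
  invisible(x)
}

#' Construct an LD correlation matrix
#'
#' @param r symmetric numeric matrix of pairwise LD correlations in `[-1, 1]`
#'   with unit diagonal.
#' @param variant_ids variant identifiers (row/column names).
#' @return A named symmetric matrix of class `ld_matrix`.
#' @export
ld_matrix <- function(r, variant_ids = rownames(r)) {
  r <- as.matrix(r)
  stopifnot(nrow(r) == ncol(r), length(variant_ids) == nrow(r))
  if (max(abs(r - t(r))) > 1e-8) stop("LD matrix must be symmetric", call. = FALSE)
  if (any(abs(r) > 1 + 1e-8)) stop("LD correlations must lie in [-1, 1]", call. = FALSE)
  if (any(abs(diag(r) - 1) > 1e-8)) stop("LD matrix diagonal must be 1", call. = FALSE)
  dimnames(r) <- list(variant_ids, variant_ids)
  class(r) <- c("ld_matrix", class(r))
  r
}

#' Read an LD matrix from a tab-separated file
#'
#' Square matrix with a variant_id header row and first column.
#'
#' @param path file path.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  ld_matrix(as.matrix(df))
}

#' Write an LD matrix to a tab-separated file
#'
#' @param ld an `ld_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  df <- data.frame(variant_id = rownames(ld), unclass(ld),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Greedy LD clumping of an instrument set
#'
#' Repeatedly keeps the remaining variant with the smallest p-value (ties
#' broken by larger F statistic, then lexicographic variant_id) and removes
#' every remaining variant on the same chromosome within `window_kb` kilobases
#' whose squared LD correlation with it is at least `r2_max`. Retained
#' instruments are therefore approximately independent.
#'
#' @param inst an `instrument_set`.
#' @param ld an `ld_matrix` covering all instrument variants.
#' @param r2_max squared-correlation threshold (default 0.1).
#' @param window_kb clumping window in kb (default 10000).
#' @return The clumped `instrument_set`, rows in selection order.
#' @export
ld_clump <- function(inst, ld, r2_max = 0.1, window_kb = 10000) {
  stopifnot(inherits(inst, "instrument_set"))
  rows <- inst$rows
  if (nrow(rows) == 0L) return(inst)
  missing_ids <- setdiff(rows$variant_id, rownames(ld))
  if (length(missing_ids) > 0L) {
    stop("variant(s) missing from LD matrix: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "), call. = FALSE)
  }
  window_bp <- window_kb * 1000
  remaining <- seq_len(nrow(rows))
  picked <- integer(0)
  while (length(remaining) > 0L) {
    sub <- rows[remaining, ]
    ord <- order(sub$pval, -sub$f_stat, sub$variant_id)
    best <- remaining[ord[1L]]
    picked <- c(picked, best)
    remaining <- setdiff(remaining, best)
    if (length(remaining) > 0L) {
      r2_with_best <- ld[rows$variant_id[remaining], rows$variant_id[best]]^2
      in_window <- rows$chrom[remaining] == rows$chrom[best] &
        abs(rows$pos[remaining] - rows$pos[best]) <= window_bp
      remaining <- remaining[!(in_window & r2_with_best >= r2_max)]
    }
  }
  out <- rows[picked, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(exposure_id = inst$exposure_id, rows = out),
            class = "instrument_set")
}

# restrict a sumstats object to the instrument variants, preserving order
subset_to_instruments <- function(s, inst) {
  idx <- match(inst$rows$variant_id, s$records$variant_id)
  s$records <- s$records[idx[!is.na(idx)], , drop = FALSE]
  rownames(s$records) <- NULL
  s
}
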
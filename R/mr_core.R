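# Causal-effect estimators (Wald ratio, IVW, MR-Egger, weighted median,
# mode-based) and the sensitivity suite (Cochran's Q, Egger intercept,
# MR-PRESSO, leave-one-out, Steiger directionality, power).

Z95 <- stats::qnorm(0.975)  # 1.959964

# run expr with a temporary RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Assemble an MR estimate record
#'
#' One-row data.frame with the causal effect on the log(OR)/linear scale, its
#' standard error and p-value, and the exponentiated effect with 95% Wald
#' limits.
#'
#' @param method estimator label.
#' @param beta,se effect and standard error (log-odds scale for binary
#'   outcomes).
#' @param nsnp number of instruments used.
#' @param pval p-value; computed two-sided normal from `beta/se` when omitted.
#' @return data.frame of class `mr_estimate` with columns `method`, `nsnp`,
#'   `beta`, `se`, `pval`, `or`, `or_lo95`, `or_hi95`.
#' @export
mr_estimate <- function(method, beta, se, nsnp, pval = NULL) {
  stopifnot(is.finite(beta), is.finite(se), se > 0, nsnp >= 1)
  if (is.null(pval)) pval <- 2 * stats::pnorm(-abs(beta / se))
  structure(data.frame(method = method, nsnp = as.integer(nsnp),
                       beta = beta, se = se, pval = pval,
                       or = exp(beta),
                       or_lo95 = exp(beta - Z95 * se),
                       or_hi95 = exp(beta + Z95 * se),
                       stringsAsFactors = FALSE),
            class = c("mr_estimate", "data.frame"))
}

# pull the estimation-ready numeric vectors out of a harmonized pair
pair_vectors <- function(pair) {
  k <- kept_rows(pair)
  list(id = k$variant_id, bx = k$beta_exp, sx = k$se_exp,
       by = k$beta_out, sy = k$se_out, n = nrow(k))
}

#' Wald ratio estimate from a single instrument
#'
#' `beta = beta_out / beta_exp` with first-order standard error
#' `se_out / |beta_exp|`; two-sided normal p-value.
#'
#' @param beta_exp,se_exp instrument-exposure effect and SE (`beta_exp != 0`).
#' @param beta_out,se_out instrument-outcome effect and SE.
#' @return An [mr_estimate()] with `method = "wald_ratio"`.
#' @export
mr_wald_ratio <- function(beta_exp, se_exp, beta_out, se_out) {
  if (beta_exp == 0) stop("Wald ratio undefined for beta_exp = 0", call. = FALSE)
  mr_estimate("wald_ratio", beta_out / beta_exp, se_out / abs(beta_exp), 1L)
}

# IVW weights and per-variant ratios
ivw_terms <- function(v) {
  if (any(v$bx == 0)) stop("zero exposure effect among instruments", call. = FALSE)
  list(r = v$by / v$bx, w = v$bx^2 / v$sy^2)
}

#' Inverse-variance-weighted estimate
#'
#' The weighted mean of per-variant Wald ratios with first-order inverse-
#' variance weights `beta_exp^2 / se_out^2`; algebraically identical to
#' weighted least squares of outcome on exposure effects through the origin.
#' The default multiplicative random-effects model inflates the fixed-effect
#' standard error by `sqrt(max(1, Q/(k-1)))` so that between-instrument
#' heterogeneity widens, and can never narrow, the interval.
#'
#' @param pair a `harmonized_pair` with >= 2 usable variants (a single variant
#'   falls back to the Wald ratio).
#' @param model `"multiplicative_re"` (default) or `"fixed"`.
#' @return An [mr_estimate()].
#' @export
mr_ivw <- function(pair, model = c("multiplicative_re", "fixed")) {
  model <- match.arg(model)
  v <- pair_vectors(pair)
  if (v$n < 1) stop("no usable variants after harmonization", call. = FALSE)
  if (v$n == 1) return(mr_wald_ratio(v$bx, v$sx, v$by, v$sy))
  t <- ivw_terms(v)
  beta <- sum(t$w * t$r) / sum(t$w)
  se <- 1 / sqrt(sum(t$w))
  if (model == "multiplicative_re") {
    q <- sum(t$w * (t$r - beta)^2)
    se <- se * sqrt(max(1, q / (v$n - 1)))
  }
  mr_estimate("ivw", beta, se, v$n)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with a
#' free intercept and weights `1/se_out^2`, after orienting all exposure
#' effects non-negative. The slope estimates the causal effect; the intercept
#' estimates average directional pleiotropy and its two-sided t test (k - 2 df)
#' is the pleiotropy check. Standard errors are scaled by
#' `sqrt(max(1, RSS/(k-2)))` (no deflation under underdispersion).
#'
#' @param pair a `harmonized_pair` with >= 3 usable variants.
#' @return A list: `estimate` ([mr_estimate()] for the slope), `intercept`,
#'   `intercept_se`, `intercept_pval`.
#' @export
mr_egger <- function(pair) {
  v <- pair_vectors(pair)
  if (v$n < 3) stop("MR-Egger needs at least 3 instruments", call. = FALSE)
  flip <- sign(v$bx)
  flip[flip == 0] <- 1
  bx <- v$bx * flip
  by <- v$by * flip
  w <- 1 / v$sy^2
  X <- cbind(intercept = 1, slope = bx)
  xtwx <- crossprod(X, X * w)
  if (abs(det(xtwx)) < 1e-12 * prod(diag(xtwx) + 1e-300) ||
      stats::var(bx) < 1e-14 * mean(bx^2)) {
    stop("rank-deficient Egger design: no variation in exposure effects",
         call. = FALSE)
  }
  coef <- solve(xtwx, crossprod(X, by * w))
  resid <- by - X %*% coef
  df <- v$n - 2L
  sigma2 <- sum(w * resid^2) / df
  covm <- solve(xtwx) * max(1, sigma2)
  a <- coef[1L]; b <- coef[2L]
  a_se <- sqrt(covm[1L, 1L]); b_se <- sqrt(covm[2L, 2L])
  est <- mr_estimate("egger", b, b_se, v$n,
                     pval = 2 * stats::pt(-abs(b / b_se), df))
  list(estimate = est,
       intercept = a, intercept_se = a_se,
       intercept_pval = 2 * stats::pt(-abs(a / a_se), df))
}

# interpolated weighted percentile with midpoint convention
weighted_percentile <- function(x, w, prob = 0.5) {
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (prob <= s[1L]) return(x[1L])
  if (prob >= s[length(s)]) return(x[length(x)])
  stats::approx(s, x, xout = prob, ties = "ordered")$y
}

# one parametric-bootstrap matrix of point estimates
boot_point_estimates <- function(v, n_boot, point_fun) {
  vapply(seq_len(n_boot), function(i) {
    bx <- stats::rnorm(v$n, v$bx, v$sx)
    by <- stats::rnorm(v$n, v$by, v$sy)
    point_fun(bx, by, v$sy)
  }, numeric(1))
}

#' Weighted-median estimate
#'
#' The inverse-variance-weighted median of the per-variant Wald ratios
#' (interpolated weighted 50th percentile with the midpoint convention),
#' consistent when instruments carrying more than half of the weight are
#' valid. The standard error comes from a seeded parametric bootstrap that
#' redraws exposure and outcome effects from their sampling distributions.
#'
#' @param pair a `harmonized_pair` with >= 3 usable variants.
#' @param n_boot bootstrap replicates (default 5000).
#' @param seed RNG seed for the bootstrap.
#' @return An [mr_estimate()] with `method = "weighted_median"`.
#' @export
mr_weighted_median <- function(pair, n_boot = 5000, seed = 1) {
  v <- pair_vectors(pair)
  if (v$n < 3) stop("weighted median needs at least 3 instruments", call. = FALSE)
  t <- ivw_terms(v)
  beta <- weighted_percentile(t$r, t$w)
  point_fun <- function(bx, by, sy) {
    ok <- bx != 0
    weighted_percentile(by[ok] / bx[ok], bx[ok]^2 / sy[ok]^2)
  }
  boots <- with_seed(seed, boot_point_estimates(v, n_boot, point_fun))
  se <- stats::sd(boots)
  if (!is.finite(se) || se <= 0) se <- .Machine$double.eps
  mr_estimate("weighted_median", beta, se, v$n)
}

mode_bandwidth <- function(r, bandwidth_factor) {
  spread <- min(stats::sd(r), stats::IQR(r) / 1.349)
  bandwidth_factor * 0.9 * spread * length(r)^(-1 / 5)
}

mode_point <- function(r, w, bandwidth_factor, grid_n = 512L) {
  h <- mode_bandwidth(r, bandwidth_factor)
  if (!is.finite(h) || h <= 0) return(r[1L])
  grid <- seq(min(r), max(r), length.out = grid_n)
  dens <- vapply(grid, function(x) sum(w * stats::dnorm(x, r, h)), numeric(1))
  grid[which.max(dens)]
}

#' Mode-based estimate (simple or weighted)
#'
#' The mode of a normal-kernel density over the per-variant Wald ratios,
#' located on a 512-point grid spanning the ratio range; robust when the
#' largest cluster of instruments is valid even if it carries under half the
#' weight. Bandwidth is a modified Silverman rule
#' `0.9 min(sd, IQR/1.349) k^(-1/5)` times `bandwidth_factor`. When all ratios
#' coincide (zero bandwidth) the common ratio is returned. Standard error via
#' seeded parametric bootstrap.
#'
#' @param pair a `harmonized_pair` with >= 3 usable variants.
#' @param weighted use inverse-variance weights for the kernel (`TRUE`) or
#'   uniform weights (`FALSE`, the simple mode).
#' @param bandwidth_factor multiplier on the Silverman bandwidth (default 1).
#' @param n_boot bootstrap replicates (default 5000).
#' @param seed RNG seed for the bootstrap.
#' @return An [mr_estimate()] with `method` `"weighted_mode"` or
#'   `"simple_mode"`.
#' @export
mr_mode <- function(pair, weighted = TRUE, bandwidth_factor = 1,
                    n_boot = 5000, seed = 1) {
  v <- pair_vectors(pair)
  if (v$n < 3) stop("mode estimator needs at least 3 instruments", call. = FALSE)
  t <- ivw_terms(v)
  w <- if (weighted) t$w / sum(t$w) else rep(1 / v$n, v$n)
  beta <- mode_point(t$r, w, bandwidth_factor)
  point_fun <- function(bx, by, sy) {
    ok <- bx != 0
    r <- by[ok] / bx[ok]
    wb <- if (weighted) bx[ok]^2 / sy[ok]^2 else rep(1, sum(ok))
    mode_point(r, wb / sum(wb), bandwidth_factor)
  }
  boots <- with_seed(seed, boot_point_estimates(v, n_boot, point_fun))
  se <- stats::sd(boots)
  if (!is.finite(se) || se <= 0) se <- .Machine$double.eps
  mr_estimate(if (weighted) "weighted_mode" else "simple_mode", beta, se, v$n)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_j (r_j - beta_ivw_fixed)^2` over per-variant ratios with IVW
#' weights; chi-square with k - 1 df under homogeneity. Large Q (small p)
#' flags heterogeneity across instruments, a symptom of pleiotropy.
#'
#' @param pair a `harmonized_pair` with >= 2 usable variants.
#' @return list with `q`, `df`, `pval`.
#' @export
cochran_q <- function(pair) {
  v <- pair_vectors(pair)
  if (v$n < 2) stop("Cochran's Q needs at least 2 instruments", call. = FALSE)
  t <- ivw_terms(v)
  beta <- sum(t$w * t$r) / sum(t$w)
  q <- sum(t$w * (t$r - beta)^2)
  df <- v$n - 1L
  list(q = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate excluding each instrument in turn; an estimate
#' that moves markedly when one variant is excluded flags that variant as
#' influential (a candidate outlier).
#'
#' @param pair a `harmonized_pair` with >= 3 usable variants.
#' @param model IVW model, as in [mr_ivw()].
#' @return data.frame with one row per left-out variant: `left_out`, `nsnp`,
#'   `beta`, `se`, `pval`.
#' @export
mr_leave_one_out <- function(pair, model = "multiplicative_re") {
  v <- pair_vectors(pair)
  if (v$n < 3) stop("leave-one-out needs at least 3 instruments", call. = FALSE)
  out <- lapply(seq_len(v$n), function(j) {
    sub <- pair
    sub$rows <- kept_rows(pair)[-j, , drop = FALSE]
    est <- mr_ivw(sub, model = model)
    data.frame(left_out = v$id[j], nsnp = est$nsnp, beta = est$beta,
               se = est$se, pval = est$pval, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# leave-one-out fixed-effect IVW slopes, vectorized: b_{-j} for every j
loo_slopes <- function(bx, by, sy) {
  w <- bx^2 / sy^2
  r <- by / bx
  (sum(w * r) - w * r) / (sum(w) - w)
}

#' MR-PRESSO global, outlier and distortion tests
#'
#' Residual-sum-and-outlier test for horizontal pleiotropy. The observed
#' weighted residual sum of squares uses leave-one-out IVW predictions,
#' `RSS = sum (beta_out_j - b_(-j) beta_exp_j)^2 / se_out_j^2`; its null
#' distribution is simulated by redrawing effects from their sampling
#' distributions around the leave-one-out fit. The global p-value uses
#' add-one smoothing, `(1 + #{RSS* >= RSS_obs}) / (n_sim + 1)`. Per-variant
#' outlier p-values compare each observed residual contribution with its
#' simulated distribution, flagged at the Bonferroni level
#' `outlier_alpha / k`. When outliers are found, a corrected IVW estimate on
#' the pruned set is returned together with a distortion p-value comparing the
#' observed estimate shift against shifts from removing random variant subsets
#' of the same size.
#'
#' @param pair a `harmonized_pair` with >= 4 usable variants.
#' @param n_sim simulated null replicates (default 1000).
#' @param outlier_alpha family-wise level for outlier flagging (default 0.05).
#' @param seed RNG seed.
#' @return list with `global_pval`, `outliers` (variant ids),
#'   `outlier_pvals` (named, per variant), `distortion_pval` (NULL when no
#'   outliers) and `corrected` ([mr_ivw()] on the pruned set, NULL when no
#'   outliers or too few variants remain).
#' @export
mr_presso <- function(pair, n_sim = 1000, outlier_alpha = 0.05, seed = 1) {
  v <- pair_vectors(pair)
  if (v$n < 4) stop("MR-PRESSO needs at least 4 instruments", call. = FALSE)
  k <- v$n
  b_loo <- loo_slopes(v$bx, v$by, v$sy)
  contrib_obs <- (v$by - b_loo * v$bx)^2 / v$sy^2
  rss_obs <- sum(contrib_obs)

  sim <- with_seed(seed, {
    contrib_sim <- matrix(NA_real_, n_sim, k)
    for (s in seq_len(n_sim)) {
      bx_s <- stats::rnorm(k, v$bx, v$sx)
      by_s <- stats::rnorm(k, b_loo * v$bx, v$sy)
      b_loo_s <- loo_slopes(bx_s, by_s, v$sy)
      contrib_sim[s, ] <- (by_s - b_loo_s * bx_s)^2 / v$sy^2
    }
    contrib_sim
  })
  rss_sim <- rowSums(sim)
  global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  outlier_pvals <- vapply(seq_len(k), function(j) {
    (1 + sum(sim[, j] >= contrib_obs[j])) / (n_sim + 1)
  }, numeric(1))
  names(outlier_pvals) <- v$id
  outliers <- v$id[outlier_pvals < outlier_alpha / k]

  distortion_pval <- NULL
  corrected <- NULL
  if (length(outliers) > 0L && k - length(outliers) >= 2L) {
    keep <- !(v$id %in% outliers)
    pruned <- pair
    pruned$rows <- kept_rows(pair)[keep, , drop = FALSE]
    corrected <- mr_ivw(pruned, model = "fixed")
    b_all <- mr_ivw(pair, model = "fixed")$beta
    d_obs <- b_all - corrected$beta
    n_out <- length(outliers)
    d_sim <- with_seed(seed + 1L, vapply(seq_len(n_sim), function(s) {
      drop_idx <- sample.int(k, n_out)
      sub <- pair
      sub$rows <- kept_rows(pair)[-drop_idx, , drop = FALSE]
      b_all - mr_ivw(sub, model = "fixed")$beta
    }, numeric(1)))
    distortion_pval <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (n_sim + 1)
  }
  list(global_pval = global_pval, outliers = outliers,
       outlier_pvals = outlier_pvals, distortion_pval = distortion_pval,
       corrected = corrected)
}

#' Steiger directionality test
#'
#' Compares the variance the instruments explain in the exposure with the
#' variance they explain in the outcome; a valid exposure-to-outcome
#' orientation should explain more in the exposure. The two explained
#' variances are converted to correlations, Fisher z-transformed, and compared
#' with a two-sample z test at the two traits' sample sizes. For a binary
#' outcome the outcome-side R^2 is the log-odds-scale approximation and should
#' be read as approximate.
#'
#' @param pair a `harmonized_pair` (used for allele-aligned outcome effects).
#' @param inst the `instrument_set` used for the exposure.
#' @param outcome_stats the outcome `sumstats` (for sample size and eaf).
#' @return list with `correct_direction` (TRUE when R^2 exposure strictly
#'   exceeds R^2 outcome), `pval`, `r2_exposure`, `r2_outcome`.
#' @export
mr_steiger <- function(pair, inst, outcome_stats) {
  rows <- inst$rows
  if (any(is.na(rows$eaf))) {
    stop("Steiger test requires eaf on every instrument", call. = FALSE)
  }
  k <- kept_rows(pair)
  k <- k[k$variant_id %in% rows$variant_id, , drop = FALSE]
  if (nrow(k) == 0L) stop("no instruments usable for Steiger test", call. = FALSE)
  eaf <- rows$eaf[match(k$variant_id, rows$variant_id)]
  r2_exp <- sum(variant_r2(eaf, k$beta_exp))
  eaf_out <- ifelse(is.na(k$eaf_out), eaf, k$eaf_out)
  r2_out <- sum(variant_r2(eaf_out, k$beta_out))
  n_exp <- stats::median(k$n_exp)
  n_out <- stats::median(k$n_out)
  z_exp <- atanh(min(sqrt(r2_exp), 1 - 1e-12))
  z_out <- atanh(min(sqrt(r2_out), 1 - 1e-12))
  z <- (z_exp - z_out) / sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  list(correct_direction = r2_exp > r2_out,
       pval = 2 * stats::pnorm(-abs(z)),
       r2_exposure = r2_exp, r2_outcome = r2_out)
}

#' Asymptotic power of an MR test on a binary outcome
#'
#' Normal-approximation power to detect an odds ratio `or_alt` per unit of
#' exposure, given the outcome sample size, case fraction, and the variance in
#' the exposure explained by the instruments:
#' `power = Phi(|log OR| sqrt(n r2 cf (1-cf)) - z_{1-alpha/2})`.
#' At `or_alt = 1` this returns `alpha/2` (the one-tailed margin of the
#' two-sided test), the formula's lower bound.
#'
#' @param n_outcome outcome GWAS sample size.
#' @param case_fraction case proportion in (0, 1).
#' @param r2_instruments instrument variance explained in (0, 1).
#' @param or_alt alternative odds ratio (> 0).
#' @param alpha two-sided significance level (default 0.05).
#' @return Power in (alpha/2, 1).
#' @export
mr_power <- function(n_outcome, case_fraction, r2_instruments, or_alt,
                     alpha = 0.05) {
  if (case_fraction <= 0 || case_fraction >= 1) {
    stop("case_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (r2_instruments <= 0 || r2_instruments >= 1) {
    stop("r2_instruments must lie in (0, 1)", call. = FALSE)
  }
  if (or_alt <= 0) stop("or_alt must be positive", call. = FALSE)
  ncp <- abs(log(or_alt)) *
    sqrt(n_outcome * r2_instruments * case_fraction * (1 - case_fraction))
  stats::pnorm(ncp - stats::qnorm(1 - alpha / 2))
}

#' Run all applicable MR estimators on a harmonized pair
#'
#' Wald ratio for a single instrument; IVW for two; IVW, MR-Egger, weighted
#' median and both mode estimators for three or more.
#'
#' @param pair a `harmonized_pair`.
#' @param ivw_model IVW model (see [mr_ivw()]).
#' @param n_boot bootstrap replicates for median/mode standard errors.
#' @param seed RNG seed for the bootstraps.
#' @return data.frame of [mr_estimate()] rows, one per method.
#' @export
mr_all <- function(pair, ivw_model = "multiplicative_re", n_boot = 5000,
                   seed = 1) {
  v <- pair_vectors(pair)
  if (v$n == 0) stop("no usable variants", call. = FALSE)
  if (v$n == 1) return(mr_wald_ratio(v$bx, v$sx, v$by, v$sy))
  ests <- list(mr_ivw(pair, model = ivw_model))
  if (v$n >= 3) {
    eg <- tryCatch(mr_egger(pair)$estimate, error = function(e) NULL)
    ests <- c(ests, list(
      eg,
      mr_weighted_median(pair, n_boot = n_boot, seed = seed),
      mr_mode(pair, weighted = FALSE, n_boot = n_boot, seed = seed + 1L),
      mr_mode(pair, weighted = TRUE, n_boot = n_boot, seed = seed + 2L)))
  }
  do.call(rbind, Filter(Negate(is.null), ests))
}

#' Full sensitivity report for a harmonized pair
#'
#' Bundles Cochran's Q, the MR-Egger intercept test, MR-PRESSO, the Steiger
#' directionality test and leave-one-out estimates.
#'
#' @param pair a `harmonized_pair`.
#' @param inst the exposure `instrument_set` (for Steiger).
#' @param outcome_stats the outcome `sumstats` (for Steiger).
#' @param n_sim MR-PRESSO simulations.
#' @param seed RNG seed.
#' @return list of class `sensitivity_report`.
#' @export
sensitivity_report <- function(pair, inst, outcome_stats, n_sim = 1000,
                               seed = 1) {
  v <- pair_vectors(pair)
  q <- if (v$n >= 2) cochran_q(pair) else NULL
  eg <- if (v$n >= 3) tryCatch(mr_egger(pair), error = function(e) NULL) else NULL
  pr <- if (v$n >= 4) mr_presso(pair, n_sim = n_sim, seed = seed) else NULL
  st <- tryCatch(mr_steiger(pair, inst, outcome_stats),
                 error = function(e) NULL)
  loo <- if (v$n >= 3) mr_leave_one_out(pair) else NULL
  structure(list(
    q_stat = if (is.null(q)) NA_real_ else q$q,
    q_df = if (is.null(q)) NA_integer_ else q$df,
    q_pval = if (is.null(q)) NA_real_ else q$pval,
    egger_intercept = if (is.null(eg)) NA_real_ else eg$intercept,
    egger_intercept_se = if (is.null(eg)) NA_real_ else eg$intercept_se,
    egger_intercept_pval = if (is.null(eg)) NA_real_ else eg$intercept_pval,
    presso_global_pval = if (is.null(pr)) NA_real_ else pr$global_pval,
    presso_outliers = if (is.null(pr)) character(0) else pr$outliers,
    presso_distortion_pval = if (is.null(pr)) NULL else pr$distortion_pval,
    steiger_correct_direction = if (is.null(st)) NA else st$correct_direction,
    steiger_pval = if (is.null(st)) NA_real_ else st$pval,
    loo_estimates = loo
  ), class = "sensitivity_report")
}
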
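test_that("Wald ratio divides effects and carries sign", {
  e <- mr_wald_ratio(0.5, 0.05, 0.1, 0.05)
  expect_equal(e$beta, 0.2)
  expect_equal(e$se, 0.1)
  expect_equal(e$method, "wald_ratio")

  null <- mr_wald_ratio(0.5, 0.05, 0, 0.05)
  expect_equal(null$beta, 0)
  expect_equal(null$pval, 1)

  neg <- mr_wald_ratio(-0.5, 0.05, 0.1, 0.05)
  expect_equal(neg$beta, -0.2)
  expect_equal(neg$se, 0.1)

  expect_error(mr_wald_ratio(0, 0.05, 0.1, 0.05), "beta_exp")
})

test_that("estimate records expose a consistent odds-ratio scale", {
  e <- mr_estimate("ivw", 0.3, 0.1, 5)
  expect_equal(e$or, exp(0.3))
  expect_equal(e$or_lo95, exp(0.3 - qnorm(0.975) * 0.1))
  expect_equal(e$or_hi95, exp(0.3 + qnorm(0.975) * 0.1))
  expect_true(e$or_lo95 < e$or && e$or < e$or_hi95)
})

test_that("IVW reduces to the ratio consensus and the unweighted mean", {
  # two identical variants: the common ratio
  p <- make_pair(c(0.5, 0.5), c(0.05, 0.05), c(0.1, 0.1), c(0.05, 0.05))
  expect_equal(mr_ivw(p)$beta, 0.2)

  # equal weights, ratios 0.1 and 0.3: plain mean
  p2 <- make_pair(c(0.5, 0.5), c(0.05, 0.05), c(0.05, 0.15), c(0.05, 0.05))
  expect_equal(mr_ivw(p2)$beta, 0.2)
})

test_that("IVW matches the hand-computed weighted mean and fixed SE", {
  # ratios 0.1, 0.25, 0.4 with weights 4, 1, 2 (bx = 2,1,1; sy = 1, 1, 1/sqrt2)
  bx <- c(2, 1, 1)
  sy <- c(1, 1, 1 / sqrt(2))
  by <- c(0.1, 0.25, 0.4) * bx
  p <- make_pair(bx, rep(0.01, 3), by, sy)
  e <- mr_ivw(p, model = "fixed")
  expect_equal(e$beta, 0.2071428571, tolerance = 1e-9)
  expect_equal(e$se, 0.377964473, tolerance = 1e-9)
})

test_that("a single usable variant falls back to the Wald ratio", {
  p <- make_pair(0.5, 0.05, 0.1, 0.05)
  e <- mr_ivw(p)
  expect_equal(e$method, "wald_ratio")
  expect_equal(e$beta, 0.2)
})

test_that("fixed-effect IVW equals origin-constrained WLS", {
  for (seed in 1:20) {
    k <- sample(3:10, 1)
    p <- random_pair(k, seed)
    v <- p$rows
    fit <- lm(beta_out ~ 0 + beta_exp, data = v, weights = 1 / v$se_out^2)
    e <- mr_ivw(p, model = "fixed")
    expect_equal(e$beta, unname(coef(fit)[1]), tolerance = 1e-8)
    # fixed-model SE corresponds to unit residual variance
    se_wls <- unname(sqrt(vcov(fit)[1, 1]) / summary(fit)$sigma)
    expect_equal(e$se, se_wls, tolerance = 1e-8)
  }
})

test_that("multiplicative random effects never narrows the IVW interval", {
  for (seed in 1:10) {
    p <- random_pair(6, seed)
    expect_gte(mr_ivw(p, model = "multiplicative_re")$se,
               mr_ivw(p, model = "fixed")$se)
  }
})

test_that("Egger recovers a line through the origin with zero intercept", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  p <- make_pair(bx, rep(0.01, 4), 0.5 * bx, rep(0.05, 4))
  fit <- mr_egger(p)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(fit$estimate$beta, 0.5, tolerance = 1e-10)
})

test_that("Egger equals the general weighted-least-squares oracle", {
  for (seed in 1:20) {
    k <- sample(3:10, 1)
    p <- random_pair(k, seed)
    v <- p$rows
    # orient exposure betas non-negative, as the estimator specifies
    flip <- ifelse(v$beta_exp < 0, -1, 1)
    bx <- v$beta_exp * flip
    by <- v$beta_out * flip
    w <- 1 / v$se_out^2
    fit <- lm(by ~ bx, weights = w)
    sm <- summary(fit)
    scale <- max(1, sm$sigma)  # no deflation under underdispersion
    eg <- mr_egger(p)
    expect_equal(eg$estimate$beta, unname(coef(fit)[2]), tolerance = 1e-8)
    expect_equal(eg$estimate$se, unname(sm$coefficients[2, 2] / sm$sigma * scale),
                 tolerance = 1e-8)
    expect_equal(eg$intercept, unname(coef(fit)[1]), tolerance = 1e-8)
    expect_equal(eg$intercept_se,
                 unname(sm$coefficients[1, 2] / sm$sigma * scale),
                 tolerance = 1e-8)
  }
})

test_that("Egger rejects a rank-deficient design", {
  p <- make_pair(c(0.2, 0.2, 0.2), rep(0.01, 3), c(0.1, 0.12, 0.08),
                 rep(0.05, 3))
  expect_error(mr_egger(p), "rank-deficient")
})

test_that("weighted median matches order statistics and the percentile oracle", {
  # equal weights, ratios 0.1 / 0.2 / 0.3: the middle ratio
  p <- make_pair(rep(1, 3), rep(0.01, 3), c(0.1, 0.2, 0.3), rep(0.05, 3))
  expect_equal(mr_weighted_median(p, n_boot = 100, seed = 1)$beta, 0.2)

  # consensus ratios: that value with a collapsing bootstrap SE
  p2 <- make_pair(rep(1, 3), rep(1e-6, 3), rep(0.25, 3), rep(1e-6, 3))
  e2 <- mr_weighted_median(p2, n_boot = 100, seed = 1)
  expect_equal(e2$beta, 0.25)
  expect_lt(e2$se, 1e-4)

  # unequal weights: independent interpolation oracle
  for (seed in 1:20) {
    k <- sample(4:10, 1)
    p3 <- random_pair(k, seed)
    v <- p3$rows
    r <- v$beta_out / v$beta_exp
    w <- v$beta_exp^2 / v$se_out^2
    o <- order(r)
    wn <- w[o] / sum(w)
    s_mid <- cumsum(wn) - wn / 2
    oracle <- if (0.5 <= s_mid[1]) r[o][1]
      else if (0.5 >= s_mid[k]) r[o][k]
      else approx(s_mid, r[o], xout = 0.5)$y
    expect_equal(mr_weighted_median(p3, n_boot = 10, seed = 1)$beta, oracle,
                 tolerance = 1e-8)
  }
})

test_that("mode estimators find the consensus, resisting a single outlier", {
  p <- make_pair(rep(1, 4), rep(0.01, 4), rep(0.3, 4), rep(0.05, 4))
  expect_equal(mr_mode(p, weighted = FALSE, n_boot = 50, seed = 1)$beta, 0.3)

  # ratios {0, 0, 0, 5}: mode near 0, nowhere near the mean 1.25
  p2 <- make_pair(rep(1, 4), rep(0.01, 4), c(0, 0, 0, 5), rep(0.05, 4))
  m <- mr_mode(p2, weighted = FALSE, n_boot = 50, seed = 1)$beta
  expect_lt(abs(m), 0.2)
})

test_that("the 512-point mode matches a dense-grid density oracle", {
  for (seed in 1:20) {
    k <- sample(5:10, 1)
    p <- random_tight_pair(k, seed)
    v <- p$rows
    r <- v$beta_out / v$beta_exp
    w <- rep(1 / k, k)
    h <- 0.9 * min(sd(r), IQR(r) / 1.349) * k^(-1 / 5)
    grid <- seq(min(r), max(r), length.out = 1e5)
    dens <- colSums(outer(r, grid, function(ri, g) dnorm(g, ri, h)) * w)
    oracle <- grid[which.max(dens)]
    est <- mr_mode(p, weighted = FALSE, n_boot = 10, seed = 1)$beta
    expect_equal(est, oracle, tolerance = 1e-3)
  }
})

test_that("rescaling exposure units rescales every estimator inversely", {
  p <- random_pair(8, 42)
  c0 <- 3.7
  p2 <- p
  p2$rows$beta_exp <- p$rows$beta_exp * c0
  p2$rows$se_exp <- p$rows$se_exp * c0
  expect_equal(mr_ivw(p2, model = "fixed")$beta,
               mr_ivw(p, model = "fixed")$beta / c0, tolerance = 1e-10)
  expect_equal(mr_egger(p2)$estimate$beta, mr_egger(p)$estimate$beta / c0,
               tolerance = 1e-10)
  expect_equal(mr_weighted_median(p2, n_boot = 10, seed = 1)$beta,
               mr_weighted_median(p, n_boot = 10, seed = 1)$beta / c0,
               tolerance = 1e-10)
  expect_equal(mr_mode(p2, n_boot = 10, seed = 1)$beta,
               mr_mode(p, n_boot = 10, seed = 1)$beta / c0, tolerance = 1e-6)
})

test_that("all estimators converge on the truth as instrument noise vanishes", {
  set.seed(3)
  k <- 10
  bx <- runif(k, 0.2, 0.6)
  truth <- 0.35
  p <- make_pair(bx, rep(1e-8, k), truth * bx + rnorm(k, 0, 1e-8),
                 rep(1e-6, k))
  expect_equal(mr_ivw(p)$beta, truth, tolerance = 1e-4)
  expect_equal(mr_egger(p)$estimate$beta, truth, tolerance = 1e-4)
  expect_equal(mr_weighted_median(p, n_boot = 10, seed = 1)$beta, truth,
               tolerance = 1e-4)
  expect_equal(mr_mode(p, n_boot = 10, seed = 1)$beta, truth, tolerance = 1e-3)
})

test_that("mr_all returns the method set appropriate to the instrument count", {
  expect_equal(mr_all(make_pair(0.5, 0.05, 0.1, 0.05))$method, "wald_ratio")
  expect_equal(mr_all(random_pair(2, 1), n_boot = 10)$method, "ivw")
  methods <- mr_all(random_pair(6, 1), n_boot = 10)$method
  expect_setequal(methods, c("ivw", "egger", "weighted_median",
                             "simple_mode", "weighted_mode"))
})
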
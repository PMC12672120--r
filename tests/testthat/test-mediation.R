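test_that("indirect effect follows the product rule and Sobel SE", {
  # broken first path: zero indirect effect, p = 1
  r0 <- indirect_effect(0, 0.02, 0.5, 0.1)
  expect_equal(r0$indirect, 0)
  expect_equal(r0$z, 0)
  expect_equal(r0$pval, 1)

  # hand arithmetic of the delta-method SE
  r <- indirect_effect(0.1, 0.02, 0.5, 0.1)
  expect_equal(r$indirect, 0.05)
  expect_equal(r$indirect_se, 0.01414214, tolerance = 1e-6)
  expect_equal(r$z, 3.535534, tolerance = 1e-6)

  expect_error(indirect_effect(0.1, 0, 0.5, 0.1), "positive")
  expect_error(indirect_effect(Inf, 0.02, 0.5, 0.1), "finite")
})

test_that("a z of 2.011 corresponds to a two-sided p of 0.044", {
  # reconstruct a pair of path coefficients whose product has z = 2.011
  r <- indirect_effect(2.011, 1, 1, 1e-12)
  expect_equal(r$z, 2.011, tolerance = 1e-6)
  expect_equal(round(r$pval, 3), 0.044)
})

test_that("mediated proportion and its Wald interval match the closed form", {
  full <- mediation_proportion(0.05, 0.01, 0.05)
  expect_equal(full$proportion, 1.0)

  # division consistency at the published scale: 0.009 / 0.0468 = 19.2%
  r <- mediation_proportion(0.009, 0.002, 0.0468)
  expect_equal(round(100 * r$proportion, 1), 19.2)

  # a proportion of 19.23% with z = 2.011 brackets (0.49, 37.97) in percent
  prop <- 0.1923
  z <- 2.011
  ci <- mediation_proportion(prop, prop / z, 1)
  expect_equal(round(100 * ci$lo95, 2), 0.49)
  expect_equal(round(100 * ci$hi95, 2), 37.97)

  expect_error(mediation_proportion(0.05, 0.01, 0), "beta0")
  expect_warning(neg <- mediation_proportion(-0.05, 0.01, 0.1), "discordant")
  expect_lt(neg$proportion, 0)
  expect_true(neg$inconsistent_mediation)
})

test_that("proportion intervals are symmetric and delta2 is wider", {
  r <- mediation_proportion(0.04, 0.015, 0.2)
  expect_equal(r$hi95 - r$proportion, r$proportion - r$lo95, tolerance = 1e-12)
  r2 <- mediation_proportion(0.04, 0.015, 0.2, se0 = 0.05, method = "delta2")
  expect_gt(r2$se, r$se)
  expect_equal(r2$proportion, r$proportion)
})

test_that("BH q-values match the step-up computation", {
  expect_equal(bh_fdr(rep(0.03, 4)), rep(0.03, 4))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("BH q-values are permutation-invariant, monotone and above p", {
  set.seed(12)
  p <- runif(30)^2
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  perm <- sample(30)
  expect_equal(bh_fdr(p[perm]), q[perm])
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
})

strong_mediation_cfg <- function(seed, beta2 = 0.4) {
  sim_config(n_variants = 30, beta1_true = 0.3, beta2_true = beta2,
             direct_true = 0.08, strong_fraction = 0.5,
             med_instrument_fraction = 0.3, n_med = 31684,
             case_fraction = 0.5, strong_z = c(20, 40),
             med_strong_z = c(20, 40), seed = seed)
}

test_that("mediation recovers the simulated causal triple", {
  sim <- simulate_triple(strong_mediation_cfg(101))
  res <- run_mediation(sim$exposure, sim$mediator, sim$outcome,
                       ld = sim$ld, region = sim$region)
  rep <- recovery_report(sim$truth, res)
  expect_equal(rep$true, c(0.3, 0.4, 0.2, 0.6))
  expect_lt(abs(res$beta1 - 0.3), 0.05)
  expect_lt(abs(res$beta2 - 0.4), 0.05)
  expect_lt(abs(res$beta0 - 0.2), 0.05)
  expect_lt(abs(res$proportion - 0.6), 0.15)
  expect_equal(res$indirect, res$beta1 * res$beta2)
  expect_equal(res$z, res$indirect / res$indirect_se)

  # determinism: the same inputs give the identical result
  res2 <- run_mediation(sim$exposure, sim$mediator, sim$outcome,
                        ld = sim$ld, region = sim$region)
  expect_identical(res, res2)
})

test_that("a null mediator path gives a near-zero indirect effect", {
  sim <- simulate_triple(strong_mediation_cfg(55, beta2 = 0))
  res <- run_mediation(sim$exposure, sim$mediator, sim$outcome,
                       ld = sim$ld, region = sim$region)
  expect_lt(abs(res$indirect), 0.05)
})

test_that("mediation errors are labeled with the failing step", {
  sim <- simulate_triple(strong_mediation_cfg(7))
  # remove all mediator signal so step 2 has no instruments
  flat <- sim$mediator
  flat$records$pval <- rep(0.5, nrow(flat$records))
  expect_error(run_mediation(sim$exposure, flat, sim$outcome, ld = sim$ld,
                             region = sim$region),
               "step2")
})

test_that("screening flags true effects and reports failures as NA rows", {
  sims <- lapply(1:3, function(i) {
    simulate_triple(sim_config(n_variants = 20, strong_fraction = 0.5,
                               direct_true = if (i == 1) 0.15 else 0,
                               case_fraction = 0.5, strong_z = c(15, 30),
                               seed = 300 + i))
  })
  exposures <- lapply(seq_along(sims), function(i) {
    s <- sims[[i]]$exposure
    s$trait_id <- paste0("gene", i)
    s
  })
  res <- mr_screen(exposures, sims[[1]]$outcome, ld = sims[[1]]$ld)
  expect_equal(nrow(res), 3L)
  expect_true(res$significant_raw[1])
  expect_true(all(res$fdr_q >= res$pval, na.rm = TRUE))

  # an exposure with no instruments becomes an NA row with a reason
  weak <- exposures[[2]]
  weak$records$pval <- rep(0.9, nrow(weak$records))
  res2 <- mr_screen(list(exposures[[1]], weak), sims[[1]]$outcome,
                    ld = sims[[1]]$ld)
  expect_equal(res2$reason[2], "no_instruments")
  expect_true(is.na(res2$pval[2]))

  # duplicated exposure: identical rows, family size 2 in the q-values
  res3 <- mr_screen(list(exposures[[1]], exposures[[1]]), sims[[1]]$outcome,
                    ld = sims[[1]]$ld)
  expect_equal(res3$beta[1], res3$beta[2])
  expect_equal(res3$fdr_q, p.adjust(res3$pval, method = "BH"))
})
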
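test_that("specific growth rate corrects for dilution", {
  expect_equal(specific_growth_rate(100, 200, 0, 1, 0), log(2))
  expect_equal(specific_growth_rate(100, 100, 0, 1, 0.5), log(2))
  expect_equal(specific_growth_rate(100, 100 * 0.5, 0, 1, 0.5), 0)
  expect_error(specific_growth_rate(0, 10, 0, 1), "positive")
  expect_error(specific_growth_rate(10, 10, 0, 1, 1), "dilution")
  # additive over consecutive undiluted intervals
  set.seed(2)
  F <- cumprod(c(100, exp(runif(5, -0.2, 0.8))))
  t <- 0:5
  total <- specific_growth_rate(F[1], F[6], t[1], t[6]) * 5
  steps <- sum(specific_growth_rate(F[-6], F[-1], t[-6], t[-1]))
  expect_equal(total, steps)
})

test_that("balanced-growth criteria switch on the mean growth rate", {
  # fast grower, noiseless: criterion (i)
  s <- generate_growth_series(mu = 0.7, n_days = 15, noise_cv = 0,
                              dilutions = c(rep(0, 7), 0.5, rep(0, 7)))
  chk <- balanced_growth_check(s)
  expect_true(chk$balanced)
  expect_equal(chk$criterion, "i")
  expect_equal(chk$mu_mean, 0.7)

  # slow grower with tight regression and stable Fv/Fm: criterion (ii)
  s2 <- generate_growth_series(mu = 0.3, n_days = 40, noise_cv = 0.002,
                               fv_fm_cv = 0.05, seed = 4)
  chk2 <- balanced_growth_check(s2)
  expect_equal(chk2$criterion, "ii")
  expect_true(chk2$balanced)
  expect_gt(chk2$r_squared, 0.995)

  # fast grower with noisy day-to-day rates: fails criterion (i)
  s3 <- generate_growth_series(mu = 0.6, n_days = 20, noise_cv = 0.12,
                               seed = 6)
  chk3 <- balanced_growth_check(s3)
  expect_equal(chk3$criterion, "i")
  expect_false(chk3$balanced)

  expect_error(balanced_growth_check(
    generate_growth_series(mu = 0.3, n_days = 5)), "insufficient span")
})

test_that("growth scoring is a fold-change rule with inclusive boundary", {
  flat <- fluorescence_series(0:5, rep(10, 6))
  expect_equal(score_growth(flat, blank = 9.5), "negative")
  rising <- fluorescence_series(0:5, 10 * 2^(0:5))
  expect_equal(score_growth(rising), "positive")
  exact <- fluorescence_series(0:2, c(10, 20, 50))
  expect_equal(score_growth(exact, fold_threshold = 5), "positive")
  below <- fluorescence_series(0:2, c(10, 20, 49.9))
  expect_equal(score_growth(below, fold_threshold = 5), "negative")
})

test_that("MPN maximum likelihood matches the brute-force grid oracle", {
  exp530 <- mpn_experiment(positives = c(5, 3, 0))
  est <- mpn_estimate(exp530)
  oracle <- mpn_grid_oracle(c(5, 3, 0))
  expect_lt(abs(est$mpn - oracle) / oracle, 0.01)
  expect_equal(est$censored, "none")
  expect_true(est$ci_low <= est$mpn && est$mpn <= est$ci_high)

  # a sample of non-censored outcomes (the full enumeration runs in the
  # acceptance suite)
  for (g in list(c(1, 0, 0), c(4, 2, 1), c(5, 5, 3), c(3, 3, 3))) {
    est <- mpn_estimate(mpn_experiment(positives = g))
    oracle <- mpn_grid_oracle(g)
    expect_lt(abs(est$mpn - oracle) / oracle, 0.01)
  }
})

test_that("MPN reproduces classical 5-tube table values", {
  # classical design: 10, 1, 0.1 mL inocula; published table values are
  # MPN per 100 mL, rounded to two significant figures
  classical <- function(g) {
    e <- mpn_experiment(dilution_factors = c(1, 0.1, 0.01), positives = g,
                        tube_volume = 10)
    100 * mpn_estimate(e)$mpn
  }
  published <- list("5,3,0" = 79, "5,1,0" = 33, "4,2,0" = 22,
                    "5,2,2" = 95, "5,0,0" = 23, "5,4,0" = 130,
                    "5,5,4" = 1600)
  for (key in names(published)) {
    g <- as.integer(strsplit(key, ",")[[1]])
    expect_lt(abs(classical(g) - published[[key]]) / published[[key]],
              0.03)
  }
})

test_that("censored MPN outcomes carry one-sided bounds", {
  allneg <- mpn_estimate(mpn_experiment(positives = c(0, 0, 0)))
  expect_equal(allneg$mpn, 0)
  expect_equal(allneg$censored, "all_negative")
  expect_gt(allneg$ci_high, 0)

  allpos <- mpn_estimate(mpn_experiment(positives = c(5, 5, 5)))
  expect_equal(allpos$censored, "all_positive")
  expect_true(is.finite(allpos$ci_low) && allpos$ci_low > 0)
  expect_error(mpn_experiment(positives = c(6, 0, 0)), "impossible")
})

test_that("the MPN likelihood is unimodal in log concentration", {
  lam_grid <- 10^seq(-3, 4, length.out = 400)
  for (g in list(c(5, 3, 0), c(2, 1, 0), c(5, 5, 1), c(1, 1, 1))) {
    e <- mpn_experiment(positives = g)
    v <- e$tube_volume * e$dilution_factors
    ll <- vapply(lam_grid, function(l)
      sum(g * log(1 - exp(-l * v)) + (5 - g) * (-l * v)), 0)
    signs <- sign(diff(ll))
    # once the log-likelihood starts decreasing it never rises again
    expect_lte(sum(diff(signs[signs != 0]) != 0), 1)
  }
})

test_that("viable fraction rescales the estimate and its CI", {
  res <- mpn_estimate(mpn_experiment(positives = c(5, 3, 0)))
  vf <- viable_fraction(res, res$mpn)
  expect_equal(vf$fraction, 1)
  vf2 <- viable_fraction(structure(list(mpn = 4e2, ci_low = 1e2,
                                        ci_high = 1.2e3, censored = "none"),
                                   class = "mpn_result"), 1e6)
  expect_equal(vf2$fraction, 4e-4)
  expect_equal(vf2$ci_low, 1e-4)
  allneg <- mpn_estimate(mpn_experiment(positives = c(0, 0, 0)))
  vf3 <- viable_fraction(allneg, 1e6)
  expect_equal(vf3$fraction, 0)
  expect_gt(vf3$ci_high, 0)
  expect_error(viable_fraction(res, 0), "initial_concentration")
})

test_that("simulated MPN experiments behave like the Poisson model", {
  expect_equal(generate_mpn_experiment(0, seed = 1)$positives, rep(0L, 3))
  # lambda * v1 = 20: top tier essentially always all positive
  e <- generate_mpn_experiment(40, seed = 2)   # v1 = 0.5 mL
  expect_equal(e$positives[1], 5L)
  # lambda * v2 = 1: tier-2 positive fraction ~ 1 - exp(-1)
  set.seed(3)
  hits <- replicate(400, generate_mpn_experiment(20)$positives[2])
  expect_equal(mean(hits) / 5, 1 - exp(-1), tolerance = 0.05)
})
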
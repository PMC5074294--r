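test_that("generation is deterministic given a seed", {
  a <- archetype_preset("I")
  e1 <- generate_experiment(a, n_cells = 500, n_replicates = 2, seed = 42)
  e2 <- generate_experiment(a, n_cells = 500, n_replicates = 2, seed = 42)
  expect_identical(e1, e2)
  p1 <- generate_panel(n_cells = 300, seed = 7)
  p2 <- generate_panel(n_cells = 300, seed = 7)
  expect_identical(p1, p2)
})

test_that("generated log-fluorescence matches archetype moments", {
  a <- archetype_preset("I", zero_fraction = 0)
  e <- generate_experiment(a, n_cells = 1e5, n_replicates = 1, seed = 3,
                           volume_mL = 1)
  tab <- e$replicates[[1]]$tables$untreated.FDA
  st <- log_stats(tab)
  truth_mean <- a$live$FDA$mean
  truth_sd <- a$live$FDA$sd
  n <- st$n_positive
  # replicate shift contributes archetype$replicate_sd to the mean's noise
  se_mean <- sqrt(truth_sd^2 / n + a$replicate_sd^2)
  expect_lt(abs(st$mean_log - truth_mean), 3 * se_mean)
  expect_lt(abs(st$sd_log - truth_sd), 3 * truth_sd / sqrt(2 * n))
})

test_that("mixture dead distributions carry their design moments", {
  a <- archetype_preset("IV", zero_fraction = 0, replicate_sd = 1e-6)
  dm <- dead_moments(a$dead$CMFDA)
  e <- generate_experiment(a, n_cells = 5e4, n_replicates = 1, seed = 5)
  st <- log_stats(e$replicates[[1]]$tables$heat_treated.CMFDA)
  expect_equal(st$mean_log, dm$mean, tolerance = 0.01)
  expect_equal(st$sd_log, dm$sd, tolerance = 0.02)
  # the bimodal dead distribution's upper mode exceeds the live mode
  expect_gt(max(a$dead$CMFDA$means), a$live$CMFDA$mean)
  # and the design separation is negative
  expect_lt(truth_separations(a)["CMFDA"], 0)
})

test_that("zero-fluorescence events appear at the designed fraction", {
  a0 <- archetype_preset("II", zero_fraction = 0)
  e0 <- generate_experiment(a0, n_cells = 5000, n_replicates = 1, seed = 9)
  zc <- split_zero_fluorescence(e0$replicates[[1]]$tables$untreated.FDA)
  expect_equal(zc$zero_count, 0L)

  a2 <- archetype_preset("II", zero_fraction = 0.02)
  e2 <- generate_experiment(a2, n_cells = 2e4, n_replicates = 1, seed = 9)
  zc2 <- split_zero_fluorescence(e2$replicates[[1]]$tables$untreated.FDA)
  expect_equal(zc2$zero_count / 2e4, 0.02,
               tolerance = 3 * sqrt(0.02 * 0.98 / 2e4) / 0.02)
  expect_error(archetype_preset("II", zero_fraction = 0.05), "zero_fraction")
})

test_that("heat and stain losses thin event counts binomially", {
  a <- archetype_preset("I", heat_loss = 0.5,
                        stain_loss = c(FDA = 0.4, CMFDA = 0, FDA_CMFDA = 0))
  e <- generate_experiment(a, n_cells = 2e4, n_replicates = 1, seed = 13)
  tabs <- e$replicates[[1]]$tables
  n_heat <- n_events(tabs$heat_treated.none)
  n_fda <- n_events(tabs$untreated.FDA)
  expect_equal(n_heat / 2e4, 0.5, tolerance = 3 * sqrt(0.25 / 2e4) / 0.5)
  expect_equal(n_fda / 2e4, 0.6,
               tolerance = 3 * sqrt(0.6 * 0.4 / 2e4) / 0.6)
  # heat and stain compose on the heat-treated, stained sample
  n_both <- n_events(tabs$heat_treated.FDA)
  expect_equal(n_both / 2e4, 0.3, tolerance = 0.1)
})

test_that("growth series reproduce the design growth rate", {
  s <- generate_growth_series(mu = 0.6, n_days = 10, noise_cv = 0,
                              dilutions = c(rep(0, 4), 0.5, rep(0, 5)))
  mu <- interval_growth_rates(s)
  expect_equal(mu, rep(0.6, 9))
  # flat when mu = 0
  s0 <- generate_growth_series(mu = 0, n_days = 6, noise_cv = 0)
  expect_equal(dilution_corrected(s0), rep(s0$readings[1], 6))
})

test_that("panel truth records designed consistency and accuracy", {
  archetypes <- list(
    archetype_preset("I"),
    archetype_preset("II"),
    archetype_preset("III", name = "sp_incons", replicate_sd = 0.35),
    archetype_preset("IV"))
  panel <- generate_panel(archetypes, n_cells = 300, seed = 11)
  expect_equal(unname(panel$truth$designed_consistent),
               c(TRUE, TRUE, FALSE, TRUE))
  # inconsistent species get 5 replicates, consistent get 3
  expect_equal(length(panel$species$sp_incons$replicates), 5L)
  expect_equal(length(panel$species$sp_I$replicates), 3L)
  expect_true(all(panel$truth$designed_accurate_nonparam >= 0))
  # the designed tally counts archetypes with expected corrected FN <= 5%
  expect_equal(unname(panel$truth$designed_accurate_nonparam["FDA"]),
               sum(vapply(archetypes, function(a)
                 expected_fn_rate(a, "FDA", "nonparametric") <= 5,
                 logical(1))))
})

test_that("expected error rates respect losses and zeros", {
  a <- archetype_preset("I")   # FDA separation 7: staining-perfect
  base <- expected_fn_rate(a, "FDA", "nonparametric",
                           loss_corrected = FALSE)
  # zeros dominate the expected FN when separation is large
  expect_equal(base, 100 * a$zero_fraction, tolerance = 0.05)
  lossy <- archetype_preset("I",
    stain_loss = c(FDA = 0.48, CMFDA = 0, FDA_CMFDA = 0))
  corrected <- expected_fn_rate(lossy, "FDA", "nonparametric")
  expect_gt(corrected, 48)
  expect_equal(corrected, loss_corrected_fn(base, 0.48))
})
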
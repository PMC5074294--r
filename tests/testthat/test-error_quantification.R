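# thresholds at exactly 4 on the linear scale, one per family
thr_not_dead4 <- parametric_threshold(make_log_stats(log10(4), 0), 3, "dead")
thr_not_alive4 <- parametric_threshold(make_log_stats(log10(4), 0), 3, "live")

test_that("false-negative rate applies the asymmetric boundary rule", {
  live <- toy_table(1:10)
  # not-dead threshold: events at or below 4 are dead -> 4 of 10
  expect_equal(false_negative_rate(live, thr_not_dead4), 40)
  # not-alive threshold: only events strictly below 4 are dead -> 3 of 10
  expect_equal(false_negative_rate(live, thr_not_alive4), 30)
  # all above threshold
  expect_equal(false_negative_rate(toy_table(5:14), thr_not_dead4), 0)
  expect_error(false_negative_rate(toy_table(rep(0, 3)), thr_not_dead4,
                                   include_zeros = FALSE), "insufficient")
})

test_that("false-positive rate counts dead events classified live", {
  dead <- toy_table(1:10)
  thr9 <- parametric_threshold(make_log_stats(log10(9), 0), 3, "dead")
  expect_equal(false_positive_rate(dead, thr9), 10)
  thr10 <- parametric_threshold(make_log_stats(1, 0), 3, "dead")
  expect_equal(false_positive_rate(toy_table(1:10), thr10), 0)

  # a dead sample scored against its own 95th percentile: ~5% by
  # construction (interpolation error only)
  set.seed(9)
  f <- rlnorm(4000, 2, 1)
  th <- nonparametric_threshold(toy_table(f), reference = "dead")
  expect_equal(false_positive_rate(toy_table(f), th), 5, tolerance = 0.01)
})

test_that("zero-fluorescence events classify as dead under any positive
           threshold", {
  live <- toy_table(c(0, 0, rep(100, 8)))
  expect_equal(false_negative_rate(live, thr_not_dead4), 20)
  expect_equal(false_negative_rate(live, thr_not_dead4,
                                   include_zeros = FALSE), 0)
})

test_that("separation statistic is the standardized mean difference", {
  a <- make_log_stats(3.0, 0.4)
  b <- make_log_stats(2.0, 0.5)
  expect_equal(separation_statistic(a, b), 2)
  expect_equal(separation_statistic(a, a), 0)
  # negative when dead cells stain brighter
  expect_lt(separation_statistic(make_log_stats(1, 0.2),
                                 make_log_stats(2, 0.5)), 0)
  expect_error(separation_statistic(a, make_log_stats(2, 0)), "undefined")
})

test_that("analytic error curves match a numerical-integration oracle", {
  # upper-tail oracle integrates the normal density directly
  expect_equal(analytic_fixed_rate(3), 100 * phi_upper_oracle(3),
               tolerance = 1e-8)
  expect_equal(round(analytic_fixed_rate(3), 3), 0.135)
  expect_equal(sprintf("%.2f", round(analytic_fixed_rate(3), 3)), "0.14")
  expect_equal(analytic_fixed_rate(0), 50)
  expect_equal(analytic_fixed_rate(1.645), 5.0, tolerance = 1e-3)

  expect_equal(analytic_false_negative(3, 3), 50)
  expect_equal(analytic_false_negative(3, 0),
               100 * (1 - phi_upper_oracle(3)), tolerance = 1e-8)
  expect_equal(analytic_false_negative(3, 6), 100 * phi_upper_oracle(3),
               tolerance = 1e-8)
  expect_lt(analytic_false_negative(3, 6), 0.15)
})

test_that("analytic rates are monotone in T and delta", {
  deltas <- seq(0, 8, by = 0.25)
  for (T in c(1, 2, 3)) {
    fn <- analytic_false_negative(T, deltas)
    expect_true(all(diff(fn) < 0))
  }
  fn_T <- analytic_false_negative(c(1, 2, 3), 4)
  expect_true(all(diff(fn_T) > 0))
  expect_true(all(diff(analytic_fixed_rate(c(1, 2, 3))) < 0))
})

test_that("raising a threshold never decreases FN nor increases FP", {
  set.seed(19)
  live <- toy_table(rlnorm(500, 2, 0.6))
  dead <- toy_table(rlnorm(500, 1, 0.6))
  cuts <- seq(0.5, 3.5, by = 0.25)
  fn <- fp <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    th <- parametric_threshold(make_log_stats(cuts[i], 0), 3, "dead")
    fn[i] <- false_negative_rate(live, th)
    fp[i] <- false_positive_rate(dead, th)
  }
  expect_true(all(diff(fn) >= 0))
  expect_true(all(diff(fp) <= 0))
})

test_that("empirical FN agrees with the analytic curve for normal
           log-populations", {
  n <- 2e4
  for (delta in c(2, 3, 4)) {
    pops <- normal_pops(n, mean_dead = 1.5, sd = 0.3, delta = delta,
                        seed = 100 + delta)
    th <- parametric_threshold(log_stats(pops$dead), 3, "dead")
    emp <- false_negative_rate(pops$live, th)
    expected <- analytic_false_negative(3, delta)
    # Monte-Carlo SE of the comparison: binomial counting noise plus the
    # propagated sampling noise of the estimated mean + 3 SD threshold
    # (var of mean + 3*SD is sigma^2 * (1/n + 9/(2n)) for normal samples)
    p <- expected / 100
    se <- 100 * sqrt(p * (1 - p) / n +
                       (stats::dnorm(3 - delta))^2 * 5.5 / n)
    expect_lt(abs(emp - expected), 3 * se)
  }
})

test_that("loss correction composes staining loss and misclassification", {
  expect_equal(loss_corrected_fn(0, 0.48), 48)
  expect_equal(loss_corrected_fn(10, 0), 10)
  expect_equal(loss_corrected_fn(50, 0.5), 75)
  expect_error(loss_corrected_fn(120, 0), "fn_rate")
  # corrected rate never below the uncorrected one
  set.seed(3)
  fn <- runif(20, 0, 100); loss <- runif(20)
  expect_true(all(loss_corrected_fn(fn, loss) >= fn - 1e-12))
})

test_that("accuracy verdict averages replicates and applies the loss flag", {
  rep_report <- function(fn, fp) {
    structure(list(fn_rate = fn, fp_rate = fp,
                   fn_rate_loss_corrected = fn), class = "error_report")
  }
  reps <- list(rep_report(1, 2), rep_report(2, 1), rep_report(3, 2))
  v <- accuracy_verdict(reps, stain_loss_significant = FALSE)
  expect_true(v$accurate)
  expect_true(v$accurate_no_loss)
  expect_equal(v$mean_fn, 2)

  v2 <- accuracy_verdict(list(rep_report(6, 1)), FALSE)
  expect_false(v2$accurate)

  v3 <- accuracy_verdict(list(rep_report(1, 1)), stain_loss_significant = TRUE)
  expect_true(v3$accurate)
  expect_false(v3$accurate_no_loss)
})
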
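#' False-negative rate of a live population under a threshold
#'
#' Fraction (in %) of live cells classified dead. For a statistically-not-dead
#' threshold, cells at or below the cutoff count as dead; for a
#' statistically-not-alive threshold only cells strictly below it do.
#' Zero-fluorescence events are included in the tally by default: a live cell
#' with no measurable signal is operationally a false negative (they are
#' excluded from fitting the log-normal reference, not from classification).
#' Set `include_zeros = FALSE` to restrict the denominator to events with
#' positive signal.
#'
#' @param live a gated `event_table` of the live population.
#' @param threshold a `threshold_result`.
#' @param include_zeros include zero-fluorescence events in the tally.
#' @return false-negative rate in percent.
#' @export
false_negative_rate <- function(live, threshold, include_zeros = TRUE) {
  stopifnot(inherits(live, "event_table"))
  f <- live$events$F_green
  if (!include_zeros) f <- f[f > 0]
  if (length(f) == 0) stop("insufficient data: no live events")
  100 * mean(!classify_live(f, threshold))
}

#' False-positive rate of a dead population under a threshold
#'
#' Fraction (in %) of dead cells classified live: strictly above a not-dead
#' threshold, or at-or-above a not-alive threshold.
#'
#' @param dead a gated `event_table` of the dead population.
#' @param threshold a `threshold_result`.
#' @param include_zeros include zero-fluorescence events in the tally.
#' @return false-positive rate in percent.
#' @export
false_positive_rate <- function(dead, threshold, include_zeros = TRUE) {
  stopifnot(inherits(dead, "event_table"))
  f <- dead$events$F_green
  if (!include_zeros) f <- f[f > 0]
  if (length(f) == 0) stop("insufficient data: no dead events")
  100 * mean(classify_live(f, threshold))
}

#' Separation statistic between live and dead log-fluorescence
#'
#' The dimensionless ratio (mean log live - mean log dead) / SD of the dead
#' population's log fluorescence. It governs the attainable error trade-off:
#' large values mean the populations are distinct; values near zero mean the
#' distributions overlap almost completely; negative values mean dead cells
#' stain brighter than live ones, which is inconsistent with the assumptions
#' of a vital stain.
#'
#' @param live_stats,dead_stats `log_stats` for the two populations.
#' @return the separation as a numeric scalar.
#' @export
separation_statistic <- function(live_stats, dead_stats) {
  stopifnot(inherits(live_stats, "log_stats"), inherits(dead_stats, "log_stats"))
  if (dead_stats$sd_log == 0)
    stop("undefined separation: dead population has zero log-SD")
  (live_stats$mean_log - dead_stats$mean_log) / dead_stats$sd_log
}

#' Analytic false-negative rate for normal populations
#'
#' For live and dead log-fluorescence that are normal with common SD and
#' separation `delta` (in SD units), the false-negative rate of the
#' statistically-not-dead threshold at `mean_dead + T*SD` is
#' `100 * Phi(T - delta)`. By symmetry the same curve gives the
#' false-positive rate of the statistically-not-alive threshold at
#' `mean_live - T*SD`.
#'
#' @param T standard-deviation multiplier of the threshold.
#' @param delta population separation in SD units; may be a vector.
#' @return rate in percent.
#' @export
analytic_false_negative <- function(T, delta) {
  100 * stats::pnorm(T - delta)
}

#' Statistically fixed error rate of a T-sigma threshold
#'
#' The rate imposed by construction on the reference population itself:
#' false positives for a not-dead threshold (dead cells above mean + T*SD),
#' false negatives for a not-alive threshold. Equals `100 * (1 - Phi(T))`;
#' 0.14% at T = 3.
#'
#' @param T standard-deviation multiplier; may be a vector.
#' @return rate in percent.
#' @export
analytic_fixed_rate <- function(T) {
  100 * (1 - stats::pnorm(T))
}

#' Correct a false-negative rate for cell loss on staining
#'
#' Cells lost during staining are live cells that can never be counted, so
#' they add to the false negatives. Loss and staining misclassification are
#' composed multiplicatively (independent events): the corrected rate is
#' `100 * (1 - (1 - fn/100) * (1 - loss))`.
#'
#' @param fn_rate false-negative rate in percent.
#' @param stain_loss_fraction fraction of live cells lost on staining, in
#'   \[0, 1\].
#' @return corrected rate in percent.
#' @export
loss_corrected_fn <- function(fn_rate, stain_loss_fraction) {
  if (any(fn_rate < 0 | fn_rate > 100)) stop("fn_rate must be in [0, 100]")
  if (any(stain_loss_fraction < 0 | stain_loss_fraction > 1))
    stop("stain_loss_fraction must be in [0, 1]")
  100 * (1 - (1 - fn_rate / 100) * (1 - stain_loss_fraction))
}

#' Error report for one sample
#'
#' Bundles the empirical error rates of a live/dead pair under a threshold
#' with the separation statistic and the loss-corrected false-negative rate.
#'
#' @param live,dead gated `event_table`s.
#' @param threshold a `threshold_result`.
#' @param stain_loss_fraction fraction of live cells lost on staining.
#' @param include_zeros passed to the rate functions.
#' @return An `error_report` list with `fn_rate`, `fp_rate`,
#'   `fn_rate_loss_corrected`, `separation`, `threshold`, `n_live`,
#'   `n_dead`, `stain_loss_fraction`.
#' @export
error_report <- function(live, dead, threshold, stain_loss_fraction = 0,
                         include_zeros = TRUE) {
  fn <- false_negative_rate(live, threshold, include_zeros)
  fp <- false_positive_rate(dead, threshold, include_zeros)
  sep <- tryCatch(separation_statistic(log_stats(live), log_stats(dead)),
                  error = function(e) NA_real_)
  structure(list(
    fn_rate = fn, fp_rate = fp,
    fn_rate_loss_corrected = loss_corrected_fn(fn, stain_loss_fraction),
    separation = sep, threshold = threshold,
    n_live = n_events(live), n_dead = n_events(dead),
    stain_loss_fraction = stain_loss_fraction
  ), class = "error_report")
}

#' Accuracy verdict across replicates
#'
#' A species x stain combination is classified accurately when the mean
#' loss-corrected false-negative rate and the mean false-positive rate
#' across replicates are both at most 5%. A stricter flag additionally
#' requires no significant cell loss on staining.
#'
#' @param reports list of `error_report`s, one per replicate.
#' @param stain_loss_significant logical: was cell loss on staining
#'   statistically significant for this species x stain?
#' @param fn_limit,fp_limit accuracy limits in percent (default 5 each).
#' @return list with `accurate` (error criterion only), `accurate_no_loss`
#'   (error criterion and no significant stain loss), `mean_fn`, `mean_fp`.
#' @export
accuracy_verdict <- function(reports, stain_loss_significant = FALSE,
                             fn_limit = 5, fp_limit = 5) {
  if (length(reports) < 1) stop("need at least one replicate report")
  mean_fn <- mean(vapply(reports, function(r) r$fn_rate_loss_corrected, 0))
  mean_fp <- mean(vapply(reports, function(r) r$fp_rate, 0))
  acc <- (mean_fn <= fn_limit) && (mean_fp <= fp_limit)
  list(accurate = acc,
       accurate_no_loss = acc && !stain_loss_significant,
       mean_fn = mean_fn, mean_fp = mean_fp)
}
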
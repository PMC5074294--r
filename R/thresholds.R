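#' Log-scale summary statistics of green fluorescence
#'
#' Mean and SD of log10 green fluorescence over the strictly positive events
#' of a gated sample. Per-cell fluorescence distributions are negatively
#' skewed on the linear scale and are log10-transformed to approximate
#' normality; zero-fluorescence events cannot be log-transformed and are
#' counted separately (they re-enter nonparametric analyses and, optionally,
#' classification tallies).
#'
#' @param table a gated `event_table`.
#' @return A `log_stats` list: `mean_log`, `sd_log`, `n_positive`, `n_zero`.
#' @export
log_stats <- function(table) {
  stopifnot(inherits(table, "event_table"))
  f <- table$events$F_green
  pos <- f[f > 0]
  if (length(pos) < 2)
    stop("insufficient data: need >= 2 events with F_green > 0")
  lg <- log10(pos)
  structure(list(mean_log = mean(lg), sd_log = stats::sd(lg),
                 n_positive = length(pos), n_zero = sum(f == 0)),
            class = "log_stats")
}

#' Construct a log_stats object directly
#'
#' Convenience constructor for analytic work where the moments are known
#' rather than estimated from events.
#'
#' @param mean_log,sd_log moments of log10 fluorescence.
#' @param n_positive,n_zero event counts.
#' @return A `log_stats` list.
#' @export
make_log_stats <- function(mean_log, sd_log, n_positive = 0L, n_zero = 0L) {
  if (sd_log < 0) stop("sd_log must be >= 0")
  structure(list(mean_log = mean_log, sd_log = sd_log,
                 n_positive = n_positive, n_zero = n_zero),
            class = "log_stats")
}

new_threshold <- function(value, scale, method, reference,
                          T = NA_real_, percentile = NA_real_) {
  structure(list(value = value, scale = scale, method = method,
                 reference = reference, T = T, percentile = percentile),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold> %s (%s reference): %g on %s scale\n",
              x$method, x$reference, x$value, x$scale))
  invisible(x)
}

#' Parametric classification threshold (detection-limit analogue)
#'
#' With a dead-cell reference the threshold is `mean_log + T * sd_log` of the
#' dead population's log10 fluorescence -- the analogue of an analytical
#' lower limit of detection set T standard deviations above the blank; cells
#' above it are "statistically not dead". With a live-cell reference it is
#' `mean_log - T * sd_log`; cells below it are "statistically not alive".
#' The default `T = 3` mirrors the common detection-limit criterion.
#'
#' @param stats a `log_stats` object for the reference population.
#' @param T standard-deviation multiplier (> 0).
#' @param reference `"dead"` or `"live"`.
#' @return A `threshold_result` on the log10 scale; `method` is
#'   `"parametric_not_dead"` or `"parametric_not_alive"`.
#' @export
parametric_threshold <- function(stats, T = 3, reference = c("dead", "live")) {
  stopifnot(inherits(stats, "log_stats"))
  reference <- match.arg(reference)
  if (T <= 0) stop("T must be > 0")
  if (reference == "dead")
    new_threshold(stats$mean_log + T * stats$sd_log, "log10",
                  "parametric_not_dead", "dead", T = T)
  else
    new_threshold(stats$mean_log - T * stats$sd_log, "log10",
                  "parametric_not_alive", "live", T = T)
}

#' Nonparametric (percentile) classification threshold
#'
#' The empirical percentile of green fluorescence of the reference sample on
#' the linear scale, zero-fluorescence events included. Defaults are the
#' 95th percentile of the dead population (fixing false positives at 5%) and
#' the 5th percentile of the live population (fixing false negatives at 5%).
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param table a gated `event_table` of the reference population.
#' @param percentile percentile in (0, 100); default 95 for `"dead"`, 5 for
#'   `"live"`.
#' @param reference `"dead"` or `"live"`.
#' @return A `threshold_result` on the linear scale.
#' @export
nonparametric_threshold <- function(table, percentile = NULL,
                                    reference = c("dead", "live")) {
  stopifnot(inherits(table, "event_table"))
  reference <- match.arg(reference)
  if (is.null(percentile)) percentile <- if (reference == "dead") 95 else 5
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must be in (0, 100)")
  f <- table$events$F_green
  if (length(f) == 0) stop("insufficient data: empty event table")
  value <- unname(stats::quantile(f, percentile / 100, type = 7))
  method <- if (reference == "dead") "nonparametric_not_dead"
            else "nonparametric_not_alive"
  new_threshold(value, "linear", method, reference, percentile = percentile)
}

#' Threshold value on the linear fluorescence scale
#'
#' @param threshold a `threshold_result`.
#' @return the cutoff expressed on the linear `F_green` scale.
#' @export
threshold_linear <- function(threshold) {
  stopifnot(inherits(threshold, "threshold_result"))
  if (threshold$scale == "linear") threshold$value else 10^threshold$value
}

#' Is a threshold of the statistically-not-dead family?
#'
#' Not-dead thresholds are built from the dead population and classify cells
#' at or below the cutoff as dead; not-alive thresholds are built from the
#' live population and classify cells at or above the cutoff as live. The
#' tie-breaking convention therefore differs between the two families.
#'
#' @param threshold a `threshold_result`.
#' @return logical.
#' @export
is_not_dead_threshold <- function(threshold) {
  stopifnot(inherits(threshold, "threshold_result"))
  threshold$reference == "dead"
}

#' Classify events as live or dead against a threshold
#'
#' Applies the family-specific boundary convention: for a not-dead threshold
#' cells with signal at or below the cutoff are dead; for a not-alive
#' threshold cells with signal strictly below the cutoff are dead (those at
#' or above it are live). Comparison is on the linear scale, so
#' zero-fluorescence events always classify as dead against any positive
#' cutoff.
#'
#' @param F_green vector of linear-scale green fluorescence values.
#' @param threshold a `threshold_result`.
#' @return logical vector, `TRUE` where classified live.
#' @export
classify_live <- function(F_green, threshold) {
  cut <- threshold_linear(threshold)
  if (is_not_dead_threshold(threshold)) F_green > cut else F_green >= cut
}
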
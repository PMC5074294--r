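#' Specific growth rate from successive fluorescence readings
#'
#' Growth of semicontinuous cultures is tracked from the between-day increase
#' in blank-corrected chl a fluorescence, correcting for the fraction `d` of
#' culture replaced with fresh medium between readings:
#' `mu = ln(F2 / ((1 - d) * F1)) / (t2 - t1)`, in per-day units.
#'
#' @param F1,F2 blank-corrected fluorescence at the two readings (> 0).
#' @param t1,t2 observation times in days (`t2 > t1`).
#' @param d dilution fraction in \[0, 1): proportion of culture replaced
#'   after the first reading.
#' @return specific growth rate in d^-1.
#' @export
specific_growth_rate <- function(F1, F2, t1, t2, d = 0) {
  if (any(F1 <= 0) || any(F2 <= 0)) stop("fluorescence must be positive")
  if (any(d < 0 | d >= 1)) stop("dilution d must be in [0, 1)")
  if (any(t2 <= t1)) stop("t2 must be greater than t1")
  log(F2 / ((1 - d) * F1)) / (t2 - t1)
}

#' Fluorescence time series for growth bookkeeping
#'
#' @param times observation times in days, strictly increasing.
#' @param readings blank-corrected fluorescence, positive.
#' @param dilutions fraction of culture replaced after each reading (the
#'   last entry is unused); in \[0, 1). Defaults to no dilution.
#' @param fv_fm optional variable-fluorescence ratio per observation.
#' @return A `fluorescence_series` list.
#' @export
fluorescence_series <- function(times, readings, dilutions = NULL,
                                fv_fm = NULL) {
  n <- length(times)
  if (length(readings) != n) stop("times and readings must match in length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(readings <= 0)) stop("readings must be positive")
  if (is.null(dilutions)) dilutions <- rep(0, n)
  if (length(dilutions) != n) stop("dilutions must match times in length")
  if (any(dilutions < 0 | dilutions >= 1)) stop("dilutions must be in [0, 1)")
  if (!is.null(fv_fm) && length(fv_fm) != n)
    stop("fv_fm must match times in length")
  structure(list(times = times, readings = readings, dilutions = dilutions,
                 fv_fm = fv_fm), class = "fluorescence_series")
}

#' Per-interval growth rates of a series
#'
#' @param series a `fluorescence_series`.
#' @return numeric vector of interval growth rates (length `n - 1`).
#' @export
interval_growth_rates <- function(series) {
  stopifnot(inherits(series, "fluorescence_series"))
  n <- length(series$times)
  specific_growth_rate(series$readings[-n], series$readings[-1],
                       series$times[-n], series$times[-1],
                       series$dilutions[-n])
}

#' Dilution-corrected cumulative fluorescence
#'
#' Rescales each reading by the cumulative dilution applied before it so the
#' corrected series grows as if no culture had been removed; its log is
#' linear in time under steady exponential growth.
#'
#' @param series a `fluorescence_series`.
#' @return numeric vector of corrected readings.
#' @export
dilution_corrected <- function(series) {
  stopifnot(inherits(series, "fluorescence_series"))
  n <- length(series$readings)
  keep <- cumprod(c(1, 1 - series$dilutions[-n]))
  series$readings / keep
}

#' Balanced-growth check
#'
#' A culture is accepted as being in balanced growth when, over at least 10
#' generations, either (i) the coefficients of variation of the interval
#' growth rates and of Fv/Fm are both below 10% (used for fast growers,
#' mean rate >= 0.5 d^-1), or (ii) the coefficient of determination of a
#' linear regression of log dilution-corrected fluorescence on time exceeds
#' 0.995 and the CV of Fv/Fm is below 10% (used for slow growers, whose
#' day-to-day rate estimates are too noisy for criterion i). Generations are
#' counted as elapsed time x mean rate / ln 2.
#'
#' @param series a `fluorescence_series` with `fv_fm` present.
#' @param cv_limit CV limit, as a fraction (default 0.10).
#' @param r2_limit regression limit for criterion (ii) (default 0.995).
#' @param mu_switch growth rate (d^-1) separating the two criteria.
#' @return list with `balanced` (logical), `criterion` ("i" or "ii"),
#'   `mu_mean`, `generations`, `cv_mu`, `cv_fv_fm`, `r_squared`.
#' @export
balanced_growth_check <- function(series, cv_limit = 0.10,
                                  r2_limit = 0.995, mu_switch = 0.5) {
  stopifnot(inherits(series, "fluorescence_series"))
  if (is.null(series$fv_fm)) stop("series must carry fv_fm for this check")
  mu <- interval_growth_rates(series)
  mu_mean <- mean(mu)
  span <- diff(range(series$times))
  generations <- span * mu_mean / log(2)
  if (generations < 10)
    stop(sprintf("insufficient span: %.1f generations (< 10)", generations))
  cv <- function(x) stats::sd(x) / abs(mean(x))
  cv_fv <- cv(series$fv_fm)
  cv_mu <- cv(mu)
  y <- log(dilution_corrected(series))
  fit <- stats::lm(y ~ series$times)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  if (mu_mean >= mu_switch) {
    crit <- "i"; ok <- (cv_mu < cv_limit) && (cv_fv < cv_limit)
  } else {
    crit <- "ii"; ok <- (r2 > r2_limit) && (cv_fv < cv_limit)
  }
  list(balanced = ok, criterion = crit, mu_mean = mu_mean,
       generations = generations, cv_mu = cv_mu, cv_fv_fm = cv_fv,
       r_squared = r2)
}

#' Score a dilution tube as growth-positive or -negative
#'
#' A tube is positive when its blank-corrected fluorescence rises to at
#' least `fold_threshold` times the initial blank-corrected reading at any
#' observation (inclusive boundary). The 5-fold default is a configurable
#' operational rule for distinguishing growth from drift.
#'
#' @param trajectory a `fluorescence_series` of raw tube readings.
#' @param fold_threshold fold increase required (default 5).
#' @param blank blank fluorescence to subtract.
#' @return `"positive"` or `"negative"`.
#' @export
score_growth <- function(trajectory, fold_threshold = 5, blank = 0) {
  stopifnot(inherits(trajectory, "fluorescence_series"))
  f <- trajectory$readings - blank
  if (length(f) < 2) stop("need at least 2 observations")
  init <- f[1]
  if (init <= 0) init <- .Machine$double.eps
  if (any(f[-1] >= fold_threshold * init)) "positive" else "negative"
}
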
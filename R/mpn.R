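#' Most-probable-number dilution experiment
#'
#' A serial-dilution growth assay: the parent sample is diluted in tiers
#' (typically three, separated by an order of magnitude), dispensed into
#' replicate tubes, and each tube scored positive or negative for growth.
#' Under Poisson inoculation a tube at tier i is positive with probability
#' `1 - exp(-lambda * v_i)`, where `lambda` is the viable-cell concentration
#' of the parent sample and `v_i = tube_volume * dilution_factor_i` is the
#' parent-sample volume it received.
#'
#' @param dilution_factors dilution factor per tier, ordered most- to
#'   least-concentrated (e.g. `c(1e-1, 1e-2, 1e-3)`).
#' @param positives positive-tube count per tier.
#' @param tubes_per_dilution tubes per tier (default 5).
#' @param tube_volume dispensed volume per tube in mL (default 5).
#' @return An `mpn_experiment` list.
#' @export
mpn_experiment <- function(dilution_factors = c(1e-1, 1e-2, 1e-3),
                           positives, tubes_per_dilution = 5,
                           tube_volume = 5) {
  k <- length(dilution_factors)
  if (length(positives) != k)
    stop("positives must have one entry per dilution tier")
  if (length(tubes_per_dilution) == 1)
    tubes_per_dilution <- rep(tubes_per_dilution, k)
  if (any(positives < 0 | positives > tubes_per_dilution))
    stop("impossible outcome: positives must be in [0, tubes_per_dilution]")
  if (any(dilution_factors <= 0)) stop("dilution factors must be positive")
  if (any(diff(dilution_factors) >= 0))
    stop("tiers must be ordered most- to least-concentrated")
  structure(list(dilution_factors = dilution_factors,
                 positives = as.integer(positives),
                 tubes_per_dilution = as.integer(tubes_per_dilution),
                 tube_volume = tube_volume),
            class = "mpn_experiment")
}

mpn_loglik <- function(lambda, exp) {
  v <- exp$tube_volume * exp$dilution_factors
  g <- exp$positives
  n <- exp$tubes_per_dilution
  p <- 1 - base::exp(-lambda * v)
  sum(g * log(pmax(p, .Machine$double.xmin)) + (n - g) * (-lambda * v))
}

#' Maximum-likelihood most-probable-number estimate
#'
#' Maximizes the Poisson-inoculation binomial likelihood over the viable
#' concentration `lambda` of the parent sample (1-D search on the log
#' scale), replacing published lookup tables with the model that underlies
#' them. The 95% confidence interval uses the normal approximation on
#' log10(MPN) with Cochran's standard error
#' `0.58 * sqrt(log10(a) / n)` (a = dilution ratio between tiers, n = tubes
#' per tier). All-negative outcomes give an estimate of 0 with an exact-style
#' upper bound (the concentration at which an all-negative outcome has 5%
#' probability); all-positive outcomes give the matching lower bound and an
#' infinite estimate reported as censored.
#'
#' @param exp an `mpn_experiment`.
#' @return An `mpn_result` list: `mpn` (cells/mL of parent sample),
#'   `ci_low`, `ci_high`, `censored` (one of `"none"`, `"all_negative"`,
#'   `"all_positive"`), `se_log10`.
#' @export
mpn_estimate <- function(exp) {
  stopifnot(inherits(exp, "mpn_experiment"))
  v <- exp$tube_volume * exp$dilution_factors
  g <- exp$positives
  n <- exp$tubes_per_dilution
  # dilution ratio between adjacent tiers (for Cochran's SE)
  a <- if (length(v) > 1) exp$dilution_factors[1] / exp$dilution_factors[2]
       else 10
  se <- 0.58 * sqrt(log10(a) / mean(n))
  fac <- 10^(stats::qnorm(0.975) * se)
  if (all(g == 0)) {
    hi <- -log(0.05) / sum(n * v)  # P(all 15 tubes negative) = 5%
    return(structure(list(mpn = 0, ci_low = 0, ci_high = hi,
                          censored = "all_negative", se_log10 = se),
                     class = "mpn_result"))
  }
  if (all(g == n)) {
    lo <- stats::uniroot(function(l) sum(n * log(1 - base::exp(-l * v))) -
                           log(0.05),
                         lower = 1e-12, upper = 1e12, tol = 1e-10)$root
    return(structure(list(mpn = Inf, ci_low = lo, ci_high = Inf,
                          censored = "all_positive", se_log10 = se),
                     class = "mpn_result"))
  }
  opt <- stats::optimize(function(l) mpn_loglik(base::exp(l), exp),
                         interval = log(c(1e-9 / max(v), 1e9 / min(v))),
                         maximum = TRUE, tol = 1e-12)
  mpn <- base::exp(opt$maximum)
  structure(list(mpn = mpn, ci_low = mpn / fac, ci_high = mpn * fac,
                 censored = "none", se_log10 = se),
            class = "mpn_result")
}

#' @export
print.mpn_result <- function(x, ...) {
  cat(sprintf("<mpn_result> %g cells/mL (95%% CI %g-%g)%s\n",
              x$mpn, x$ci_low, x$ci_high,
              if (x$censored != "none") paste0(" [", x$censored, "]") else ""))
  invisible(x)
}

#' Viable fraction relative to a cytometric cell count
#'
#' Normalizes an MPN viable-concentration estimate (and its confidence
#' bounds) to the initial cell concentration measured by flow cytometry. A
#' fraction whose CI includes 1 indicates a fully viable population.
#'
#' @param result an `mpn_result`.
#' @param initial_concentration cytometric concentration, cells/mL (> 0).
#' @return list with `fraction`, `ci_low`, `ci_high`, `censored`.
#' @export
viable_fraction <- function(result, initial_concentration) {
  stopifnot(inherits(result, "mpn_result"))
  if (initial_concentration <= 0)
    stop("initial_concentration must be > 0")
  list(fraction = result$mpn / initial_concentration,
       ci_low = result$ci_low / initial_concentration,
       ci_high = result$ci_high / initial_concentration,
       censored = result$censored)
}
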
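# Small fixtures shared across the suite. Everything is generated in code;
# no data files are read from disk.

# an event table with given green fluorescence and permissive metadata
toy_table <- function(F_green, ...) {
  event_table(F_green = F_green, F_red = rep(10, length(F_green)),
              ssc = rep(10, length(F_green)), ...)
}

# empirical quantile oracle: linear interpolation between order statistics,
# written out longhand so it is independent of stats::quantile
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# standard normal upper-tail oracle by numerical integration, independent
# of pnorm
phi_upper_oracle <- function(z) {
  stats::integrate(function(x) exp(-x^2 / 2) / sqrt(2 * pi), z, Inf,
                   rel.tol = 1e-10)$value
}

# brute-force MPN oracle: likelihood maximum on a dense log-spaced grid
mpn_grid_oracle <- function(positives, dilution_factors = c(1e-1, 1e-2, 1e-3),
                            tubes = 5, tube_volume = 5,
                            grid = 10^seq(-4, 4, length.out = 40001)) {
  v <- tube_volume * dilution_factors
  ll <- vapply(grid, function(lam) {
    p <- 1 - exp(-lam * v)
    if (any(p == 0 & positives > 0)) return(-Inf)
    sum(positives * log(pmax(p, 1e-300)) + (tubes - positives) * (-lam * v))
  }, numeric(1))
  grid[which.max(ll)]
}

# a two-population sample (live/dead) from log10-normal distributions
normal_pops <- function(n, mean_dead, sd, delta, seed) {
  set.seed(seed)
  list(dead = toy_table(10^rnorm(n, mean_dead, sd),
                        treatment = "heat_treated"),
       live = toy_table(10^rnorm(n, mean_dead + delta * sd, sd)))
}
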
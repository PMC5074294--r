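#!/usr/bin/env Rscript
# Growth bookkeeping and MPN viability validation. Checks balanced-growth
# criteria on simulated semicontinuous cultures, then estimates viable
# concentrations of untreated and heat-killed cultures from simulated
# dilution assays and normalizes them to the cytometric cell count.

library(cytovital)

set.seed(5)
dir.create("results", showWarnings = FALSE)

# balanced growth: a fast grower under criterion (i), a slow grower
# under criterion (ii)
fast <- generate_growth_series(mu = 0.7, n_days = 15, noise_cv = 0.03,
                               dilutions = c(rep(0, 7), 0.5, rep(0, 7)),
                               fv_fm_cv = 0.03, seed = 51)
slow <- generate_growth_series(mu = 0.3, n_days = 40, noise_cv = 0.002,
                               fv_fm_cv = 0.04, seed = 52)
for (nm in c("fast", "slow")) {
  chk <- balanced_growth_check(get(nm))
  cat(sprintf(
    "%s grower: mu = %.2f /d, %.0f generations, criterion (%s), %s\n",
    nm, chk$mu_mean, chk$generations, chk$criterion,
    if (chk$balanced) "balanced" else "not balanced"))
}

# MPN viability: untreated culture at 1e6 cells/mL (fully viable) vs
# heat-killed remnant at 400 viable cells/mL
init_conc <- 1e6
rows <- list()
for (case in list(list(name = "untreated", lambda = 1e6,
                       tiers = c(1e-5, 1e-6, 1e-7)),
                  list(name = "heat_treated", lambda = 400,
                       tiers = c(1e-2, 1e-3, 1e-4)))) {
  e <- generate_mpn_experiment(case$lambda, dilution_factors = case$tiers)
  r <- mpn_estimate(e)
  vf <- viable_fraction(r, init_conc)
  rows[[case$name]] <- data.frame(
    treatment = case$name, positives = paste(e$positives, collapse = "/"),
    mpn_per_mL = r$mpn, ci_low = r$ci_low, ci_high = r$ci_high,
    viable_fraction = vf$fraction,
    ci_includes_full_viability = vf$ci_low <= 1 && 1 <= vf$ci_high)
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/mpn_viability.csv", row.names = FALSE)
cat("\nMPN viability (initial concentration", format(init_conc), "/mL):\n")
print(tab, row.names = FALSE, digits = 3)
cat("\nThe untreated CI includes the cytometric count (fully viable);\n")
cat("the heat-treated viable fraction is",
    sprintf("%.3f%%", 100 * tab$viable_fraction[2]),
    "- orders of magnitude below 1.\n")
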
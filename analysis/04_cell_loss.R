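#!/usr/bin/env Rscript
# Heat- and stain-induced cell loss. Normalizes each replicate's 2 x 4
# concentration grid to its untreated/unstained cell, tests heat and
# stain effects by two-way ANOVA with interaction, and reports Tukey HSD
# contrasts against the reference cell where the ANOVA is significant.

library(cytovital)

PANEL_SEED <- 1
panel <- generate_panel(n_cells = 5000, seed = PANEL_SEED)
dir.create("results", showWarnings = FALSE)

rows <- list()
for (sp in names(panel$species)) {
  grids <- lapply(panel$species[[sp]]$replicates,
                  function(r) normalize_grid(r$grid))
  res <- heat_stain_anova(grids)
  row <- data.frame(species = sp, band_heat = res$band_heat,
                    band_stain = res$band_stain,
                    band_interaction = res$band_interaction,
                    heat_pct = NA, FDA_pct = NA, CMFDA_pct = NA,
                    FDA_CMFDA_pct = NA)
  if (any(c(res$p_heat, res$p_stain, res$p_interaction) <= 0.05,
          na.rm = TRUE)) {
    tk <- tukey_contrasts(grids, res)
    for (i in seq_len(nrow(tk))) {
      if (tk$significant[i])
        row[[paste0(sub("^heat$", "heat", tk$contrast[i]), "_pct")]] <-
          sprintf("%.1f +/- %.1f", tk$percent_change[i], tk$se[i])
    }
  }
  rows[[sp]] <- row
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/cell_loss_table.csv", row.names = FALSE)

cat("Cell-loss summary (significance bands; percent change +/- SE where\n")
cat("significant by Tukey HSD at P <= 0.05):\n\n")
print(tab, row.names = FALSE)
cat("\nDesigned heat losses were",
    paste(sprintf("%s: %.0f%%", names(panel$species),
                  100 * vapply(panel$species,
                               function(s) s$truth$heat_loss, 0)),
          collapse = ", "), "\n")
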
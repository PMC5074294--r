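#' Average cell diameter from cross-sectional area
#'
#' The diameter of the circle with the cell's measured cross-sectional
#' area: `ACD = 2 * sqrt(area / pi)`.
#'
#' @param area cross-sectional area in um^2 (> 0).
#' @return diameter in um.
#' @export
acd_from_area <- function(area) {
  if (any(area <= 0)) stop("area must be > 0")
  2 * sqrt(area / pi)
}

#' Cross-sectional area from average cell diameter
#'
#' @param acd diameter in um (> 0).
#' @return area in um^2.
#' @export
area_from_acd <- function(acd) {
  if (any(acd <= 0)) stop("acd must be > 0")
  pi * (acd / 2)^2
}

#' Apparent brightness at the classification threshold
#'
#' The threshold fluorescence normalized to cell cross-sectional area -- a
#' proxy for how bright a just-classifiable live cell would appear under
#' epifluorescence microscopy. The threshold should be
#' attenuation-reconciled before cross-species comparison.
#'
#' @param threshold a `threshold_result` (linear value used).
#' @param cross_sectional_area area in um^2 (> 0).
#' @return intensity per um^2.
#' @export
apparent_brightness <- function(threshold, cross_sectional_area) {
  if (any(cross_sectional_area <= 0)) stop("area must be > 0")
  threshold_linear(threshold) / cross_sectional_area
}

stain_levels <- c("FDA", "CMFDA", "FDA_CMFDA")

sample_thresholds <- function(live, dead, T = 3) {
  list(
    parametric_not_dead = parametric_threshold(log_stats(dead), T, "dead"),
    parametric_not_alive = parametric_threshold(log_stats(live), T, "live"),
    nonparametric_not_dead = nonparametric_threshold(dead, reference = "dead"),
    nonparametric_not_alive = nonparametric_threshold(live, reference = "live")
  )
}

#' Run the full staining-study analysis over a simulated panel
#'
#' Orchestrates every stage of the analysis on the output of
#' [generate_panel()]: gating, zero-fluorescence accounting, log statistics,
#' threshold construction (parametric and nonparametric, both references),
#' per-replicate error reports, cell-loss correction, species x stain
#' accuracy tallies, 8-point staining signatures with Bray-Curtis
#' consistency labels, 3-point separation signatures with hierarchical
#' clustering, and the heat/stain two-way ANOVA with Tukey contrasts.
#' Deterministic given the panel and configuration.
#'
#' @param panel result of [generate_panel()].
#' @param gate a [gate_spec()] applied to every sample.
#' @param T parametric threshold multiplier.
#' @param cut_distance tree-cut height for separation-signature clustering.
#' @param consistency_cutoff Bray-Curtis cutoff in percent.
#' @param include_zeros include zero-fluorescence events in classification
#'   tallies for parametric thresholds.
#' @return A `study_report` list with elements `samples` (per species x
#'   stain x replicate error table), `thresholds`, `signatures`,
#'   `consistency`, `clustering`, `cell_loss`, `accuracy` (tally per
#'   method x stain, with and without the no-stain-loss criterion), and
#'   `truth` carried over from the panel.
#' @export
run_pipeline <- function(panel, gate = gate_spec(), T = 3,
                         cut_distance = 2, consistency_cutoff = 95,
                         include_zeros = TRUE) {
  if (is.null(panel$species)) stop("panel must be a generate_panel() result")
  species_names <- names(panel$species)
  methods <- c("parametric_not_dead", "nonparametric_not_dead",
               "nonparametric_not_alive")

  sig8 <- list(); sig3 <- list(); sig3_meta <- list()
  sample_rows <- list(); thresholds <- list()
  cell_loss <- list(); consistency <- list()
  reports <- list()  # reports[[sp]][[stain]][[method]] = list of error_report

  for (sp in species_names) {
    exp <- panel$species[[sp]]
    n_rep <- length(exp$replicates)
    if (n_rep < 1) stop("no replicates for species ", sp)
    grids <- list(); sig8_sp <- list()
    for (r in seq_len(n_rep)) {
      rep_data <- exp$replicates[[r]]
      tabs <- lapply(rep_data$tables, gate_events, gate = gate)
      missing <- setdiff(as.vector(outer(c("untreated", "heat_treated"),
                                         c("none", stain_levels),
                                         paste, sep = ".")), names(tabs))
      if (length(missing))
        stop("species ", sp, ": missing sample ", missing[1])
      mean_logs <- vapply(tabs, function(t) log_stats(t)$mean_log, 0)
      sig8_sp[[r]] <- staining_signature(mean_logs[
        paste(rep(c("untreated", "heat_treated"), each = 4),
              rep(c("none", stain_levels), 2), sep = ".")])
      seps <- vapply(stain_levels, function(st)
        separation_statistic(log_stats(tabs[[paste0("untreated.", st)]]),
                             log_stats(tabs[[paste0("heat_treated.", st)]])),
        0)
      sig3[[length(sig3) + 1]] <- separation_signature(seps)
      sig3_meta[[length(sig3_meta) + 1]] <-
        data.frame(species = sp, replicate = r)
      grids[[r]] <- normalize_grid(rep_data$grid)
      for (st in stain_levels) {
        live <- tabs[[paste0("untreated.", st)]]
        dead <- tabs[[paste0("heat_treated.", st)]]
        ths <- sample_thresholds(live, dead, T)
        thresholds[[paste(sp, st, r, sep = ".")]] <- ths
        for (m in methods) {
          er <- error_report(live, dead, ths[[m]],
                             include_zeros = include_zeros)
          reports[[sp]][[st]][[m]][[r]] <- er
          sample_rows[[length(sample_rows) + 1]] <- data.frame(
            species = sp, stain = st, replicate = r, method = m,
            fn_rate = er$fn_rate, fp_rate = er$fp_rate,
            separation = er$separation,
            n_live = er$n_live, n_dead = er$n_dead)
        }
      }
    }
    consistency[[sp]] <- consistency_classification(sig8_sp,
                                                    consistency_cutoff)
    sig8[[sp]] <- sig8_sp

    anova_res <- heat_stain_anova(grids)
    tukey <- NULL
    if (any(c(anova_res$p_heat, anova_res$p_stain,
              anova_res$p_interaction) <= 0.05, na.rm = TRUE))
      tukey <- tukey_contrasts(grids, anova_res)
    cell_loss[[sp]] <- list(anova = anova_res, tukey = tukey,
                            grids = grids)
  }

  # stain-loss significance and magnitude per species x stain (for the
  # loss-corrected accuracy criterion)
  stain_loss_info <- function(sp, st) {
    tk <- cell_loss[[sp]]$tukey
    if (is.null(tk)) return(list(significant = FALSE, fraction = 0))
    row <- tk[tk$contrast == st, ]
    sig <- nrow(row) == 1 && isTRUE(row$significant) &&
      row$percent_change < 0
    frac <- if (sig) min(max(-row$percent_change / 100, 0), 1) else 0
    list(significant = sig, fraction = frac)
  }

  # each threshold imposes one error rate by construction (5% false
  # positives for the nonparametric not-dead threshold, 5% false negatives
  # for not-alive, 0.14% expected false positives for the parametric
  # 3-SD threshold), so accuracy is scored on the unconstrained error type
  accuracy <- list()
  for (m in methods) {
    scored_on_fn <- grepl("not_dead$", m)
    tal <- matrix(0L, 2, length(stain_levels),
                  dimnames = list(c("accurate", "accurate_no_loss"),
                                  stain_levels))
    per_species <- list()
    for (st in stain_levels) {
      for (sp in species_names) {
        sl <- stain_loss_info(sp, st)
        reps <- lapply(reports[[sp]][[st]][[m]], function(er) {
          er$fn_rate_loss_corrected <- loss_corrected_fn(er$fn_rate,
                                                         sl$fraction)
          er
        })
        v <- accuracy_verdict(reps, sl$significant,
                              fn_limit = if (scored_on_fn) 5 else Inf,
                              fp_limit = if (scored_on_fn) Inf else 5)
        per_species[[paste(sp, st, sep = ".")]] <- v
        tal["accurate", st] <- tal["accurate", st] + v$accurate
        tal["accurate_no_loss", st] <-
          tal["accurate_no_loss", st] + v$accurate_no_loss
      }
    }
    accuracy[[m]] <- list(tally = tal, per_species = per_species)
  }

  clustering <- cluster_separation_signatures(sig3, cut_distance)
  clustering$meta <- do.call(rbind, sig3_meta)

  structure(list(
    samples = do.call(rbind, sample_rows),
    thresholds = thresholds,
    signatures = list(sig8 = sig8, sig3 = sig3),
    consistency = consistency,
    clustering = clustering,
    cell_loss = cell_loss,
    accuracy = accuracy,
    truth = panel$truth
  ), class = "study_report")
}

#' Threshold-versus-size table for cross-species comparison
#'
#' For each species, the statistically-not-alive nonparametric threshold
#' (5th percentile of live-cell fluorescence), attenuation-reconciled,
#' tabulated against average cell diameter together with the apparent
#' brightness per unit cross-sectional area.
#'
#' @param thresholds named list of `threshold_result`s, one per species.
#' @param areas named numeric vector of cross-sectional areas (um^2).
#' @param attenuation_od named numeric vector of ODs (0 or 2) per species.
#' @return data.frame with `species`, `acd_um`, `threshold_reconciled`,
#'   `apparent_brightness`.
#' @export
threshold_size_table <- function(thresholds, areas, attenuation_od) {
  sp <- names(thresholds)
  if (is.null(sp) || !all(sp %in% names(areas)) ||
      !all(sp %in% names(attenuation_od)))
    stop("thresholds, areas and attenuation_od must share species names")
  rows <- lapply(sp, function(s) {
    val <- reconcile_attenuation(threshold_linear(thresholds[[s]]),
                                 attenuation_od[[s]])
    data.frame(species = s, acd_um = acd_from_area(areas[[s]]),
               threshold_reconciled = val,
               apparent_brightness = val / areas[[s]])
  })
  do.call(rbind, rows)
}
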
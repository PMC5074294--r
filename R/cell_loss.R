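#' Concentration grid for one replicate experiment
#'
#' Cell concentrations over the 2 x 4 grid of treatment (untreated,
#' heat-treated) by stain (none, FDA, CMFDA, FDA+CMFDA).
#'
#' @param concentrations 2 x 4 numeric matrix, rows `untreated` and
#'   `heat_treated`, columns `none`, `FDA`, `CMFDA`, `FDA_CMFDA`; all
#'   entries > 0.
#' @return A `concentration_grid` matrix with canonical dimnames.
#' @export
concentration_grid <- function(concentrations) {
  m <- as.matrix(concentrations)
  if (!all(dim(m) == c(2, 4))) stop("grid must be 2 x 4")
  if (any(m <= 0)) stop("all concentrations must be > 0")
  dimnames(m) <- list(c("untreated", "heat_treated"),
                      c("none", "FDA", "CMFDA", "FDA_CMFDA"))
  structure(m, class = c("concentration_grid", "matrix"))
}

#' Normalize a concentration grid to its untreated/unstained cell
#'
#' Dividing every entry by the untreated, unstained concentration of the
#' same replicate removes between-experiment differences in culture density
#' before treatment effects are tested; the reference entry becomes exactly
#' 1.
#'
#' @param grid a `concentration_grid`.
#' @return the normalized grid (dimensionless).
#' @export
normalize_grid <- function(grid) {
  stopifnot(inherits(grid, "concentration_grid"))
  ref <- grid["untreated", "none"]
  if (ref <= 0) stop("reference (untreated, unstained) must be > 0")
  out <- grid / ref
  class(out) <- class(grid)
  out
}

grids_to_long <- function(grids) {
  if (length(grids) < 2) stop("need at least 2 replicate grids")
  do.call(rbind, lapply(seq_along(grids), function(i) {
    g <- grids[[i]]
    stopifnot(inherits(g, "concentration_grid"))
    data.frame(
      value = as.vector(g),
      heat = factor(rep(rownames(g), 4),
                    levels = c("untreated", "heat_treated")),
      stain = factor(rep(colnames(g), each = 2),
                     levels = c("none", "FDA", "CMFDA", "FDA_CMFDA")),
      replicate = i
    )
  }))
}

#' Two-way ANOVA of heat and stain effects on normalized concentrations
#'
#' Standard two-factor ANOVA with interaction on the normalized
#' concentration grids, with replicate experiments providing the error
#' degrees of freedom. Significance bands follow the usual convention: `-`
#' for P >= 0.05, `*` < 0.05, `**` < 0.01, `***` < 0.001.
#'
#' @param grids list of >= 2 normalized `concentration_grid`s.
#' @return list with `p_heat`, `p_stain`, `p_interaction`, matching
#'   `band_*` strings, the `aov` `fit`, and the long-format `data`.
#' @export
heat_stain_anova <- function(grids) {
  dat <- grids_to_long(grids)
  fit <- stats::aov(value ~ heat * stain, data = dat)
  tab <- summary(fit)[[1]]
  p <- tab[["Pr(>F)"]]
  band <- function(p) {
    if (is.na(p) || p >= 0.05) "-"
    else if (p < 0.001) "***" else if (p < 0.01) "**" else "*"
  }
  list(p_heat = p[1], p_stain = p[2], p_interaction = p[3],
       band_heat = band(p[1]), band_stain = band(p[2]),
       band_interaction = band(p[3]), fit = fit, data = dat)
}

#' Tukey HSD contrasts against the untreated, unstained reference
#'
#' Run only when the two-way ANOVA is significant (P <= 0.05 on at least
#' one factor). Performs Tukey's honestly-significant-difference test over
#' all pairwise comparisons of the 8 grid cells and reports the contrasts
#' of interest: heat-treated/unstained vs reference, and each stained
#' untreated cell vs reference, as mean percent change +/- SE across
#' replicates with a significance flag at P <= 0.05.
#'
#' @param grids list of normalized `concentration_grid`s.
#' @param anova_result result of [heat_stain_anova()] on the same grids.
#' @return data.frame with columns `contrast`, `percent_change`, `se`,
#'   `p_adj`, `significant`.
#' @export
tukey_contrasts <- function(grids, anova_result) {
  ps <- c(anova_result$p_heat, anova_result$p_stain,
          anova_result$p_interaction)
  if (!any(ps <= 0.05, na.rm = TRUE))
    stop("precondition: two-way ANOVA is not significant at P <= 0.05")
  dat <- grids_to_long(grids)
  dat$cell <- interaction(dat$heat, dat$stain, sep = ".")
  fit <- stats::aov(value ~ cell, data = dat)
  hsd <- stats::TukeyHSD(fit)$cell
  ref <- "untreated.none"
  wanted <- c(heat = "heat_treated.none",
              FDA = "untreated.FDA",
              CMFDA = "untreated.CMFDA",
              FDA_CMFDA = "untreated.FDA_CMFDA")
  out <- lapply(names(wanted), function(nm) {
    cellname <- wanted[[nm]]
    key1 <- paste(cellname, ref, sep = "-")
    key2 <- paste(ref, cellname, sep = "-")
    row <- if (key1 %in% rownames(hsd)) hsd[key1, ]
           else -hsd[key2, c(1, 3, 2, 4)] * c(1, 1, 1, -1)
    p_adj <- if (key1 %in% rownames(hsd)) hsd[key1, "p adj"]
             else hsd[key2, "p adj"]
    vals <- 100 * (dat$value[dat$cell == cellname] - 1)
    data.frame(contrast = nm,
               percent_change = mean(vals),
               se = stats::sd(vals) / sqrt(length(vals)),
               p_adj = p_adj,
               significant = p_adj <= 0.05)
  })
  do.call(rbind, out)
}
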
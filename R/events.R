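#' Per-cell cytometry event tables
#'
#' An `event_table` holds the per-cell measurements for one sample: green
#' (stain) fluorescence, red (chl a) fluorescence and side scatter, together
#' with the sample metadata needed downstream (species, treatment, stain,
#' replicate, analyzed volume, and the optical density of any neutral-density
#' filter in front of the detectors).
#'
#' @param F_green,F_red,ssc numeric vectors of equal length; per-event
#'   intensities in instrument arbitrary units. Must be non-negative.
#' @param species character scalar, species label.
#' @param treatment `"untreated"` or `"heat_treated"`.
#' @param stain one of `"none"`, `"FDA"`, `"CMFDA"`, `"FDA_CMFDA"`.
#' @param replicate integer replicate id.
#' @param volume_mL volume of sample analyzed, in mL (> 0).
#' @param attenuation_od optical density of the neutral-density filter used
#'   during acquisition; 0 (none) or 2 (99% attenuation).
#' @return An object of class `event_table`: a list with elements `events`
#'   (data.frame with columns `F_green`, `F_red`, `ssc`), `species`,
#'   `treatment`, `stain`, `replicate`, `volume_mL`, `attenuation_od`.
#' @export
event_table <- function(F_green, F_red = NULL, ssc = NULL,
                        species = "unknown", treatment = "untreated",
                        stain = "none", replicate = 1L,
                        volume_mL = 1, attenuation_od = 0) {
  n <- length(F_green)
  if (is.null(F_red)) F_red <- rep(1, n)
  if (is.null(ssc)) ssc <- rep(1, n)
  if (length(F_red) != n || length(ssc) != n)
    stop("F_green, F_red and ssc must have equal length")
  for (nm in c("F_green", "F_red", "ssc")) {
    v <- get(nm)
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad))
      stop(sprintf("negative or non-finite %s at row %d", nm, bad[1]))
  }
  treatment <- match.arg(treatment, c("untreated", "heat_treated"))
  stain <- match.arg(stain, c("none", "FDA", "CMFDA", "FDA_CMFDA"))
  if (!is.numeric(volume_mL) || volume_mL <= 0)
    stop("volume_mL must be > 0")
  if (!attenuation_od %in% c(0, 2))
    stop("attenuation_od must be 0 or 2")
  structure(list(
    events = data.frame(F_green = as.numeric(F_green),
                        F_red = as.numeric(F_red),
                        ssc = as.numeric(ssc)),
    species = species, treatment = treatment, stain = stain,
    replicate = as.integer(replicate), volume_mL = volume_mL,
    attenuation_od = attenuation_od
  ), class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %s / %s / %s / rep %d: %d events in %g mL (OD %g)\n",
              x$species, x$treatment, x$stain, x$replicate,
              nrow(x$events), x$volume_mL, x$attenuation_od))
  invisible(x)
}

#' Number of events in an event table
#' @param table an `event_table`.
#' @return integer event count.
#' @export
n_events <- function(table) {
  stopifnot(inherits(table, "event_table"))
  nrow(table$events)
}

#' Read an event table from delimited text
#'
#' Files carry metadata in `# key: value` comment lines before the header and
#' must contain columns `F_green`, `F_red` and `ssc`. This is the plain-text
#' interchange format written by [write_event_table()].
#'
#' @param path path to a CSV/TSV file.
#' @param sep field separator (default `,`).
#' @return An [event_table()].
#' @export
read_event_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  dat <- utils::read.table(text = lines[!grepl("^#", lines)], sep = sep,
                           header = TRUE, stringsAsFactors = FALSE)
  for (col in c("F_green", "F_red", "ssc"))
    if (!col %in% names(dat))
      stop("missing required column: ", col)
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  event_table(
    F_green = dat$F_green, F_red = dat$F_red, ssc = dat$ssc,
    species = if (is.null(meta$species)) "unknown" else meta$species,
    treatment = if (is.null(meta$treatment)) "untreated" else meta$treatment,
    stain = if (is.null(meta$stain)) "none" else meta$stain,
    replicate = as.integer(num(meta$replicate, 1)),
    volume_mL = num(meta$volume_mL, 1),
    attenuation_od = num(meta$attenuation_od, 0)
  )
}

#' Write an event table to delimited text
#'
#' @param table an `event_table`.
#' @param path destination file.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "event_table"))
  meta <- sprintf("# %s: %s",
                  c("species", "treatment", "stain", "replicate",
                    "volume_mL", "attenuation_od"),
                  c(table$species, table$treatment, table$stain,
                    table$replicate, table$volume_mL, table$attenuation_od))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(table$events, con, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Rectangular gate specification
#'
#' Events are gated on chl a (red) fluorescence and side scatter to exclude
#' particles other than phytoplankton. The gate is rectangular: a lower bound
#' on `F_red` and an optional band on side scatter.
#'
#' @param f_red_min lower bound on red fluorescence (events must exceed it).
#' @param ssc_min,ssc_max optional side-scatter band (inclusive).
#' @return A `gate_spec` list.
#' @export
gate_spec <- function(f_red_min = 0, ssc_min = -Inf, ssc_max = Inf) {
  if (f_red_min < 0) stop("f_red_min must be >= 0")
  if (ssc_min > ssc_max) stop("ssc_min must be <= ssc_max")
  structure(list(f_red_min = f_red_min, ssc_min = ssc_min,
                 ssc_max = ssc_max), class = "gate_spec")
}

#' Gate events on red fluorescence and side scatter
#'
#' Retains events with `F_red > f_red_min` and side scatter within
#' `[ssc_min, ssc_max]`; metadata are unchanged. Gating is idempotent.
#'
#' @param table an `event_table`.
#' @param gate a [gate_spec()].
#' @return The gated `event_table`.
#' @export
gate_events <- function(table, gate = gate_spec()) {
  stopifnot(inherits(table, "event_table"), inherits(gate, "gate_spec"))
  if (nrow(table$events) == 0) stop("cannot gate an empty event table")
  keep <- table$events$F_red > gate$f_red_min &
    table$events$ssc >= gate$ssc_min & table$events$ssc <= gate$ssc_max
  if (!any(keep))
    stop("empty population: all events removed by gate")
  table$events <- table$events[keep, , drop = FALSE]
  rownames(table$events) <- NULL
  table
}

#' Separate zero-fluorescence events
#'
#' Cells that exceed the red-fluorescence gate but register no green
#' fluorescence are scored as `F_green = 0`; they are excluded from
#' parametric statistics on log-transformed data but retained in all
#' nonparametric analyses. This helper splits them out and counts them.
#'
#' @param table a gated `event_table`.
#' @return list with `positive` (an `event_table` of events with
#'   `F_green > 0`) and `zero_count`.
#' @export
split_zero_fluorescence <- function(table) {
  stopifnot(inherits(table, "event_table"))
  pos <- table$events$F_green > 0
  out <- table
  out$events <- table$events[pos, , drop = FALSE]
  rownames(out$events) <- NULL
  list(positive = out, zero_count = sum(!pos))
}

#' Cell concentration from event count and analyzed volume
#'
#' @param table a gated `event_table`.
#' @return cells per mL.
#' @export
cell_concentration <- function(table) {
  stopifnot(inherits(table, "event_table"))
  if (table$volume_mL <= 0) stop("volume_mL must be > 0")
  nrow(table$events) / table$volume_mL
}

#' Undo neutral-density attenuation
#'
#' Samples acquired behind a 2-OD neutral-density filter are attenuated by
#' 99%; multiplying by `10^OD` reconciles intensities across instrument
#' configurations. Applied only for cross-species comparisons (threshold vs
#' cell size), never before within-sample threshold or error computation.
#'
#' @param value fluorescence intensity (or vector).
#' @param attenuation_od 0 or 2.
#' @return reconciled intensity.
#' @export
reconcile_attenuation <- function(value, attenuation_od) {
  if (!all(attenuation_od %in% c(0, 2)))
    stop("unsupported attenuation OD: ", attenuation_od[1])
  value * 10^attenuation_od
}
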
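#' Oxygen flux from a concentration slope
#'
#' Converts a chamber oxygen-concentration slope (nmol/mL/min) into a
#' whole-chamber oxygen flux (nmol O2/min). Consumption (falling
#' concentration) is reported positive. A rising concentration yields a
#' negative flux which is returned, not clipped, with a QC flag.
#'
#' @param slope Oxygen-concentration slope in nmol/mL/min (per-minute,
#'   as produced by [estimate_slope()]).
#' @param chamber_volume Chamber volume in mL (> 0). The respirometer
#'   assay mixture in the colon protocol totals 2.1 mL.
#' @param tissue_grams Optional grams of tissue in the chamber, enabling
#'   the per-gram flux.
#' @param source_window Optional `c(t_start, t_end)` provenance, seconds.
#' @return An `oxygen_flux`: list with `J_O2` (nmol O2/min, positive =
#'   consumption), `per_gram` (nmol O2/min/g or `NA`), `source_window`,
#'   `qc_flags` (character).
#' @export
oxygen_flux <- function(slope, chamber_volume, tissue_grams = NULL,
                        source_window = c(NA_real_, NA_real_)) {
  if (!is.finite(slope)) stop("`slope` must be finite")
  if (!is.finite(chamber_volume) || chamber_volume <= 0)
    stop("`chamber_volume` must be > 0 mL")
  j <- -slope * chamber_volume
  qc <- character(0)
  if (j < 0)
    qc <- "negative_flux: oxygen concentration rising over the window"
  per_gram <- NA_real_
  if (!is.null(tissue_grams) && !is.na(tissue_grams)) {
    if (tissue_grams <= 0) stop("`tissue_grams` must be > 0")
    per_gram <- j / tissue_grams
  }
  structure(
    list(J_O2 = j, per_gram = per_gram, source_window = source_window,
         qc_flags = qc),
    class = "oxygen_flux"
  )
}

#' @export
print.oxygen_flux <- function(x, ...) {
  cat(sprintf("<oxygen_flux> J_O2 = %.6g nmol O2/min", x$J_O2))
  if (!is.na(x$per_gram)) cat(sprintf(" (%.6g nmol O2/min/g)", x$per_gram))
  cat("\n")
  if (length(x$qc_flags)) cat("  QC:", paste(x$qc_flags, collapse = "; "), "\n")
  invisible(x)
}

#' Respiratory control ratio
#'
#' Ratio of state-3 (ADP-stimulated) to state-2 (substrate only, no
#' added ADP) oxygen flux. Higher values indicate better-coupled
#' mitochondria; the colon controls in the source assays average about 4.
#'
#' @param state3,state2 [oxygen_flux()] objects or bare fluxes in
#'   nmol O2/min.
#' @return The unitless ratio.
#' @export
rcr <- function(state3, state2) {
  j3 <- if (inherits(state3, "oxygen_flux")) state3$J_O2 else as.numeric(state3)
  j2 <- if (inherits(state2, "oxygen_flux")) state2$J_O2 else as.numeric(state2)
  if (!is.finite(j2) || j2 <= 0)
    stop("RCR undefined: state-2 flux must be > 0")
  j3 / j2
}

#' Segment a respirometry trace into state 2 and state 3
#'
#' State 2 begins when tissue homogenate is injected into the chamber
#' (substrate already present, no added ADP) and state 3 when ADP is
#' added. The state-2 slope is measured over a window ending at the ADP
#' event and starting at least `settle_time` after the homogenate event;
#' the state-3 slope over a window starting `settle_time` after ADP.
#' Both are converted to fluxes via [oxygen_flux()] and the RCR attached.
#'
#' @param trace An oxygen-concentration [ts_trace()] carrying a
#'   `homogenate` and an `ADP` injection event.
#' @param chamber_volume Chamber volume in mL; defaults to the trace's
#'   `chamber_volume_ml` metadata.
#' @param settle_time Seconds to discard after each injection before
#'   measuring (default 60 s).
#' @param window_length Measurement-window length in seconds
#'   (default 120 s).
#' @param tissue_grams Optional tissue mass for per-gram fluxes;
#'   defaults to the trace's `tissue_grams` metadata.
#' @return A `respiration_states`: list with `state2`, `state3`
#'   ([oxygen_flux()] each), `rcr`, `qc_flags`.
#' @export
segment_states <- function(trace, chamber_volume = NULL, settle_time = 60,
                           window_length = 120, tissue_grams = NULL) {
  stopifnot(inherits(trace, "ts_trace"))
  if (trace$channel != "oxygen_conc")
    stop("`segment_states` needs an oxygen_conc trace")
  if (is.null(chamber_volume))
    chamber_volume <- trace$metadata$chamber_volume_ml
  if (is.null(chamber_volume))
    stop("`chamber_volume` not given and no chamber_volume_ml metadata")
  if (is.null(tissue_grams)) tissue_grams <- trace$metadata$tissue_grams
  for (lab in c("homogenate", "ADP"))
    if (is.na(event_time(trace, lab, required = FALSE)))
      stop(sprintf("segmentation failed: trace has no '%s' event", lab))
  t_hom <- event_time(trace, "homogenate")
  t_adp <- event_time(trace, "ADP")
  if (t_adp <= t_hom)
    stop("segmentation failed: ADP event precedes the homogenate event")

  w2 <- c(max(t_adp - window_length, t_hom + settle_time), t_adp)
  w3 <- c(t_adp + settle_time,
          min(t_adp + settle_time + window_length, max(trace$times)))
  if (w2[1] >= w2[2])
    stop("segmentation failed: no state-2 window between homogenate settle and ADP")
  if (w3[1] >= w3[2])
    stop("segmentation failed: trace ends before the state-3 window opens")

  s2 <- estimate_slope(trace, window = w2)
  s3 <- estimate_slope(trace, window = w3)
  f2 <- oxygen_flux(s2$slope, chamber_volume, tissue_grams, s2$window)
  f3 <- oxygen_flux(s3$slope, chamber_volume, tissue_grams, s3$window)
  if (f2$J_O2 <= 0)
    stop(sprintf("RCR undefined: state-2 flux is %.4g nmol O2/min (<= 0)",
                 f2$J_O2))
  structure(
    list(state2 = f2, state3 = f3, rcr = rcr(f3, f2),
         qc_flags = c(f2$qc_flags, f3$qc_flags)),
    class = "respiration_states"
  )
}

#' @export
print.respiration_states <- function(x, ...) {
  cat(sprintf(paste0(
    "<respiration_states>\n",
    "  state 2: %.6g nmol O2/min  (window [%g, %g] s)\n",
    "  state 3: %.6g nmol O2/min  (window [%g, %g] s)\n",
    "  RCR:     %.6g\n"),
    x$state2$J_O2, x$state2$source_window[1], x$state2$source_window[2],
    x$state3$J_O2, x$state3$source_window[1], x$state3$source_window[2],
    x$rcr))
  if (length(x$qc_flags)) cat("  QC:", paste(x$qc_flags, collapse = "; "), "\n")
  invisible(x)
}

#' Single-state oxygen flux (e.g. fatty-acid oxidation assays)
#'
#' Fatty-acid-oxidation runs start with a homogenate injection and have
#' no ADP transition; the flux is measured from one window after the
#' injection settles.
#'
#' @inheritParams segment_states
#' @return An [oxygen_flux()].
#' @export
single_state_flux <- function(trace, chamber_volume = NULL, settle_time = 60,
                              window_length = 120, tissue_grams = NULL) {
  stopifnot(inherits(trace, "ts_trace"))
  if (is.null(chamber_volume))
    chamber_volume <- trace$metadata$chamber_volume_ml
  if (is.null(chamber_volume))
    stop("`chamber_volume` not given and no chamber_volume_ml metadata")
  if (is.null(tissue_grams)) tissue_grams <- trace$metadata$tissue_grams
  t_hom <- event_time(trace, "homogenate")
  w <- c(t_hom + settle_time,
         min(t_hom + settle_time + window_length, max(trace$times)))
  if (w[1] >= w[2])
    stop("trace ends before the measurement window opens")
  s <- estimate_slope(trace, window = w)
  oxygen_flux(s$slope, chamber_volume, tissue_grams, s$window)
}
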
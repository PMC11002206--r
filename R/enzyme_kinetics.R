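#' Electrons carried per substrate molecule
#'
#' Redox bookkeeping used to express enzyme rates in electron-flux
#' units: NADH and DCPIP are two-electron carriers, cytochrome c is a
#' one-electron carrier, and each O2 reduced to water at complex IV
#' accepts four electrons.
#'
#' @return Named numeric vector of electrons per carrier molecule.
#' @export
electron_equivalents <- function() {
  c(NADH = 2, DCPIP = 2, cytochrome_c = 1, O2 = 4, DTNB_thiolate = NA_real_)
}

#' Spectrophotometric assay configuration
#'
#' Holds the optical constants and volumes that convert an absorbance
#' slope into a reaction rate via Beer-Lambert: epsilon (mM^-1 cm^-1)
#' at the assay wavelength, cuvette pathlength, assay volume, and the
#' expected direction of absorbance change (NADH and DCPIP are consumed,
#' so absorbance falls; reduced cytochrome c and the DTNB thiolate
#' accumulate, so absorbance rises).
#'
#' @param enzyme One of `"complex_I"`, `"complex_II"`, `"complex_III"`,
#'   `"complex_IV"`, `"citrate_synthase"`.
#' @param epsilon Extinction coefficient, mM^-1 cm^-1 (> 0).
#' @param wavelength Assay wavelength, nm.
#' @param pathlength Optical pathlength, cm (> 0).
#' @param assay_volume Reaction volume, mL (> 0).
#' @param sample_volume Homogenate aliquot, uL (informational).
#' @param carrier Followed chromophore/substrate, one of
#'   `names(electron_equivalents())`.
#' @param direction `"decrease"` or `"increase"` — the absorbance
#'   direction that corresponds to enzymatic activity.
#' @return An `assay_config` list.
#' @seealso [default_assay_configs()] for the pre-populated per-enzyme
#'   values.
#' @export
assay_config <- function(enzyme = c("complex_I", "complex_II", "complex_III",
                                    "complex_IV", "citrate_synthase"),
                         epsilon, wavelength = NA_real_, pathlength = 1,
                         assay_volume, sample_volume = NA_real_,
                         carrier = c("NADH", "DCPIP", "cytochrome_c", "O2",
                                     "DTNB_thiolate"),
                         direction = c("decrease", "increase")) {
  enzyme <- match.arg(enzyme)
  carrier <- match.arg(carrier)
  direction <- match.arg(direction)
  if (!is.finite(epsilon) || epsilon <= 0)
    stop("`epsilon` must be > 0 mM^-1 cm^-1")
  if (!is.finite(pathlength) || pathlength <= 0)
    stop("`pathlength` must be > 0 cm")
  if (!is.finite(assay_volume) || assay_volume <= 0)
    stop("`assay_volume` must be > 0 mL")
  structure(
    list(enzyme = enzyme, epsilon = epsilon, wavelength = wavelength,
         pathlength = pathlength, assay_volume = assay_volume,
         sample_volume = sample_volume, carrier = carrier,
         direction = direction),
    class = "assay_config"
  )
}

#' Default per-enzyme assay configurations
#'
#' Pre-populated with the colon-homogenate assay constants: complex I
#' follows NADH oxidation at 340 nm (epsilon 6.22 mM^-1 cm^-1, 2 mL
#' cuvette), complex II DCPIP reduction at 600 nm (19.1, 0.2 mL),
#' complex III cytochrome c reduction at 550 nm (18.7, 0.2 mL), and
#' citrate synthase the DTNB thiolate at 412 nm (13.6). The citrate
#' synthase plate assay's pathlength and final volume are not fixed by
#' the instrument: the defaults here (1 cm, 0.25 mL) are placeholders
#' and a warning urges setting both from the actual plate geometry.
#'
#' @param cs_pathlength,cs_assay_volume Citrate synthase plate-well
#'   pathlength (cm) and reaction volume (mL). Using the defaults emits
#'   a warning.
#' @return Named list of [assay_config()] objects.
#' @export
default_assay_configs <- function(cs_pathlength = NULL,
                                  cs_assay_volume = NULL) {
  if (is.null(cs_pathlength) || is.null(cs_assay_volume)) {
    warning(paste("citrate synthase pathlength/assay volume not supplied;",
                  "defaulting to 1 cm and 0.25 mL — set these from your",
                  "plate geometry"), call. = FALSE)
    if (is.null(cs_pathlength)) cs_pathlength <- 1
    if (is.null(cs_assay_volume)) cs_assay_volume <- 0.25
  }
  list(
    complex_I = assay_config("complex_I", epsilon = 6.22, wavelength = 340,
                             pathlength = 1, assay_volume = 2,
                             sample_volume = 100, carrier = "NADH",
                             direction = "decrease"),
    complex_II = assay_config("complex_II", epsilon = 19.1, wavelength = 600,
                              pathlength = 1, assay_volume = 0.2,
                              sample_volume = 20, carrier = "DCPIP",
                              direction = "decrease"),
    complex_III = assay_config("complex_III", epsilon = 18.7,
                               wavelength = 550, pathlength = 1,
                               assay_volume = 0.2, sample_volume = 20,
                               carrier = "cytochrome_c",
                               direction = "increase"),
    citrate_synthase = assay_config("citrate_synthase", epsilon = 13.6,
                                    wavelength = 412,
                                    pathlength = cs_pathlength,
                                    assay_volume = cs_assay_volume,
                                    sample_volume = 200,
                                    carrier = "DTNB_thiolate",
                                    direction = "increase")
  )
}

#' Beer-Lambert conversion of an absorbance slope to a reaction rate
#'
#' `|slope| / (epsilon * pathlength)` gives the concentration rate in
#' mM/min; multiplying by the assay volume (mL) and 1000 gives
#' nmol carrier/min. The result is positive when the slope direction
#' matches the configured direction of enzymatic change; an opposing
#' slope (beyond `tol` AU/min) is returned negative with a QC flag, as
#' it usually signals an inverted or mislabelled trace.
#'
#' @param slope Absorbance slope, AU/min.
#' @param config An [assay_config()].
#' @param tol Direction-mismatch tolerance in AU/min (default 1e-6).
#' @return Rate in nmol carrier/min with attributes `qc_flags`
#'   (character) and `enzyme`.
#' @export
beer_lambert_rate <- function(slope, config, tol = 1e-6) {
  stopifnot(inherits(config, "assay_config"))
  if (!is.finite(slope)) stop("`slope` must be finite")
  signed <- if (config$direction == "decrease") -slope else slope
  rate <- signed / (config$epsilon * config$pathlength) *
    config$assay_volume * 1000
  qc <- character(0)
  if (signed < -tol)
    qc <- sprintf("direction_mismatch: absorbance %s but expected %s (possible inverted trace)",
                  if (slope > 0) "rising" else "falling", config$direction)
  structure(rate, qc_flags = qc, enzyme = config$enzyme)
}

#' Subtract a non-enzymatic background rate
#'
#' Each enzyme assay is paired with an inhibited run whose residual
#' (non-enzymatic) rate is subtracted from the total. A negative net
#' rate is returned as-is with a QC flag — never clipped — so
#' over-subtraction stays visible downstream.
#'
#' @param total,background Rates in nmol/min from the same
#'   [assay_config()] (compared via their `enzyme` attribute when
#'   present).
#' @return Net rate with attributes `qc_flags` and `enzyme`.
#' @export
subtract_background <- function(total, background) {
  et <- attr(total, "enzyme")
  eb <- attr(background, "enzyme")
  if (!is.null(et) && !is.null(eb) && !identical(et, eb))
    stop(sprintf("background/total assay configs disagree: %s vs %s", et, eb))
  net <- as.numeric(total) - as.numeric(background)
  qc <- c(attr(total, "qc_flags"), attr(background, "qc_flags"))
  if (net < 0)
    qc <- c(qc, "negative_net_rate: background exceeds total")
  structure(net, qc_flags = qc, enzyme = et)
}

#' Convert a carrier rate to electron flux
#'
#' @param rate Rate in nmol carrier/min.
#' @param carrier One of `"NADH"`, `"DCPIP"`, `"cytochrome_c"`, `"O2"`.
#' @return Electron flux in nmol e-/min (`rate` times the electrons per
#'   carrier, see [electron_equivalents()]).
#' @export
to_electron_flux <- function(rate, carrier) {
  eq <- electron_equivalents()
  if (!carrier %in% names(eq) || is.na(eq[[carrier]]))
    stop(sprintf("no electron equivalence for carrier '%s' (known: %s)",
                 carrier,
                 paste(names(eq)[!is.na(eq)], collapse = ", ")))
  as.numeric(rate) * eq[[carrier]]
}

#' Citrate synthase activity from an absorbance trace
#'
#' Citrate synthase releases CoASH, which reacts with DTNB to form the
#' 412-nm-absorbing thiolate; the initial linear rise, converted via
#' Beer-Lambert and divided by the grams of tissue in the assay
#' aliquot, gives the activity in nmol citrate/min/g. Citrate synthase
#' is the mitochondrial-content marker all other rates are normalized
#' against.
#'
#' @param trace An absorbance [ts_trace()].
#' @param config The citrate-synthase [assay_config()].
#' @param tissue_grams_in_aliquot Grams of source tissue represented in
#'   the assayed aliquot (> 0).
#' @param window Optional slope window, seconds (default: whole trace).
#' @return A `cs_activity`: list with `rate` (nmol citrate/min/g),
#'   `rate_assay` (nmol/min in the well), `qc_flags`.
#' @export
citrate_synthase_activity <- function(trace, config, tissue_grams_in_aliquot,
                                      window = NULL) {
  stopifnot(inherits(trace, "ts_trace"), inherits(config, "assay_config"))
  if (config$enzyme != "citrate_synthase")
    stop("`config` must be the citrate_synthase assay config")
  if (!is.finite(tissue_grams_in_aliquot) || tissue_grams_in_aliquot <= 0)
    stop("`tissue_grams_in_aliquot` must be > 0 g")
  sl <- estimate_slope(trace, window = window)
  rate_assay <- beer_lambert_rate(sl$slope, config)
  rate <- as.numeric(rate_assay) / tissue_grams_in_aliquot
  qc <- attr(rate_assay, "qc_flags")
  if (rate < 0) qc <- c(qc, "negative_cs_rate")
  structure(list(rate = rate, rate_assay = as.numeric(rate_assay),
                 qc_flags = qc),
            class = "cs_activity")
}

#' @export
print.cs_activity <- function(x, ...) {
  cat(sprintf("<cs_activity> %.6g nmol citrate/min/g\n", x$rate))
  if (length(x$qc_flags)) cat("  QC:", paste(x$qc_flags, collapse = "; "), "\n")
  invisible(x)
}

#' Complex IV activity as oxygen consumption
#'
#' Complex IV is assayed polarographically: ascorbate/TMPD keep
#' cytochrome c reduced and the homogenate's oxygen consumption after
#' injection is the activity. Electron flux is four electrons per O2.
#'
#' @param trace An oxygen-concentration [ts_trace()] with a
#'   `homogenate` injection event.
#' @param chamber_volume Chamber volume, mL.
#' @param settle_time,window_length Measurement window placement,
#'   seconds (as in [single_state_flux()]).
#' @param tissue_grams Optional tissue mass for per-gram rates.
#' @return An `enzyme_activity` (see [quantify_enzyme()]) with carrier
#'   `"O2"`.
#' @export
complex_iv_activity <- function(trace, chamber_volume, settle_time = 60,
                                window_length = 120, tissue_grams = NULL) {
  flux <- single_state_flux(trace, chamber_volume, settle_time,
                            window_length, tissue_grams)
  new_enzyme_activity(
    enzyme = "complex_IV", carrier = "O2",
    rate_substrate = flux$J_O2,
    rate_per_gram = flux$per_gram,
    background = 0, background_subtracted = FALSE,
    qc_flags = c(flux$qc_flags,
                 "no_background_trace: background assumed 0")
  )
}

new_enzyme_activity <- function(enzyme, carrier, rate_substrate,
                                rate_per_gram = NA_real_, background = 0,
                                background_subtracted = TRUE,
                                qc_flags = character(0)) {
  ef <- to_electron_flux(rate_substrate, carrier)
  efg <- if (is.na(rate_per_gram)) NA_real_
         else to_electron_flux(rate_per_gram, carrier)
  structure(
    list(enzyme = enzyme, carrier = carrier,
         rate_substrate = rate_substrate, rate_per_gram = rate_per_gram,
         electron_flux = ef, electron_flux_per_gram = efg,
         background = background,
         background_subtracted = background_subtracted,
         qc_flags = qc_flags),
    class = "enzyme_activity"
  )
}

#' Quantify an ETC complex from absorbance traces
#'
#' Runs the full spectrophotometric chain for complexes I-III: slope
#' extraction (steepest initial window for complex I, where the fastest
#' rate right after NADH addition is the measurand; fixed window
#' otherwise), Beer-Lambert conversion, background subtraction from the
#' paired inhibited trace, per-gram normalization, and electron-flux
#' units.
#'
#' @param trace Absorbance [ts_trace()] of the uninhibited assay.
#' @param config The enzyme's [assay_config()].
#' @param background_trace Optional absorbance trace of the inhibited
#'   (non-enzymatic) run; when absent the background defaults to 0 with
#'   a QC note.
#' @param tissue_grams Grams of tissue represented in the assayed
#'   aliquot, for per-gram rates (optional).
#' @param mode,window,window_length Passed to [estimate_slope()];
#'   `mode = NULL` picks `steepest_window` for complex I and
#'   `fixed_window` otherwise.
#' @return An `enzyme_activity`: list with `rate_substrate`
#'   (nmol carrier/min), `rate_per_gram`, `electron_flux` (nmol e-/min),
#'   `electron_flux_per_gram`, `background`, `background_subtracted`,
#'   `qc_flags`.
#' @export
quantify_enzyme <- function(trace, config, background_trace = NULL,
                            tissue_grams = NULL, mode = NULL,
                            window = NULL, window_length = 30) {
  stopifnot(inherits(trace, "ts_trace"), inherits(config, "assay_config"))
  if (is.null(mode))
    mode <- if (config$enzyme == "complex_I") "steepest_window"
            else "fixed_window"
  sl <- estimate_slope(trace, window = window, mode = mode,
                       window_length = window_length)
  total <- beer_lambert_rate(sl$slope, config)
  qc <- character(0)
  if (!is.null(background_trace)) {
    slb <- estimate_slope(background_trace, window = window, mode = mode,
                          window_length = window_length)
    bg <- beer_lambert_rate(slb$slope, config)
  } else {
    bg <- structure(0, enzyme = config$enzyme)
    qc <- "no_background_trace: background assumed 0"
  }
  net <- subtract_background(total, bg)
  per_gram <- NA_real_
  if (!is.null(tissue_grams) && !is.na(tissue_grams)) {
    if (tissue_grams <= 0) stop("`tissue_grams` must be > 0")
    per_gram <- as.numeric(net) / tissue_grams
  }
  new_enzyme_activity(
    enzyme = config$enzyme, carrier = config$carrier,
    rate_substrate = as.numeric(net), rate_per_gram = per_gram,
    background = as.numeric(bg),
    background_subtracted = !is.null(background_trace),
    qc_flags = c(attr(net, "qc_flags"), qc)
  )
}

#' @export
print.enzyme_activity <- function(x, ...) {
  cat(sprintf(
    "<enzyme_activity> %s: %.6g nmol %s/min = %.6g nmol e-/min\n",
    x$enzyme, x$rate_substrate, x$carrier, x$electron_flux))
  if (!is.na(x$rate_per_gram))
    cat(sprintf("  per gram: %.6g nmol/min/g (%.6g nmol e-/min/g)\n",
                x$rate_per_gram, x$electron_flux_per_gram))
  if (length(x$qc_flags)) cat("  QC:", paste(x$qc_flags, collapse = "; "), "\n")
  invisible(x)
}

#' Normalize an electron flux to mitochondrial content
#'
#' Citrate synthase activity is the mitochondrial-content marker: an
#' electron flux per gram of tissue divided by the citrate synthase
#' rate per gram (the per-minute terms cancel) yields
#' nmol e- per nmol citrate, comparable across animals regardless of
#' mitochondrial abundance.
#'
#' @param electron_flux_per_gram nmol e-/min/g.
#' @param cs A [citrate_synthase_activity()] result or a bare rate in
#'   nmol citrate/min/g (> 0).
#' @return Normalized activity, nmol e-/nmol citrate.
#' @export
normalize_to_cs <- function(electron_flux_per_gram, cs) {
  cs_rate <- if (inherits(cs, "cs_activity")) cs$rate else as.numeric(cs)
  if (!is.finite(cs_rate) || cs_rate <= 0)
    stop("normalization undefined: citrate synthase rate must be > 0")
  if (!is.finite(electron_flux_per_gram))
    stop("`electron_flux_per_gram` must be finite")
  electron_flux_per_gram / cs_rate
}
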
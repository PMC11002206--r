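# Seed hygiene: generators restore the caller's RNG state so that a
# spec with a seed is reproducible without clobbering the session RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic assay trace
#'
#' Forward model of the three assay channels: a piecewise-linear latent
#' signal whose slopes are implied by the target rates and the chamber
#' or assay volume, with slope changes at injection events, plus i.i.d.
#' Gaussian noise. Deterministic for a given seed.
#'
#' Kind-specific parameters:
#' \describe{
#'   \item{respirometry}{`state2_flux`, `state3_flux` (nmol O2/min,
#'     whole chamber), `chamber_volume` (mL), `o2_init` (nmol/mL,
#'     default 450 — the chamber is oxygenated before tissue addition).
#'     Default events: homogenate at 60 s, ADP at 360 s. Oxygen falls
#'     at `state2_flux / chamber_volume` between the two events and at
#'     `state3_flux / chamber_volume` after ADP.}
#'   \item{fluorescence}{`J_H2O2` (nmol/min), `calib_slope` (AU/uM),
#'     `chamber_volume` (mL), `baseline_au` (default 50). Fluorescence
#'     rises at `J_H2O2 / chamber_volume * calib_slope` AU/min after
#'     the homogenate event (default at 60 s).}
#'   \item{absorbance}{`activity` plus `background_rate` (nmol/min; the
#'     trace slope reflects their sum — generate a second trace with
#'     `activity = 0` to emulate the inhibited background run),
#'     `epsilon` (mM^-1 cm^-1), `pathlength` (cm), `assay_volume` (mL),
#'     `direction` (`"decrease"` or `"increase"`), `start_value` (AU).}
#' }
#'
#' @param kind `"respirometry"`, `"fluorescence"` or `"absorbance"`.
#' @param ... Kind-specific parameters as above.
#' @param events Data.frame of injection events (`time`, `label`),
#'   strictly increasing in time; `NULL` uses the kind's default
#'   schedule.
#' @param noise_sd Gaussian noise SD in signal units (>= 0, default 0).
#' @param sampling_interval Seconds between samples (default 2).
#' @param duration Trace length in seconds (default 600).
#' @param seed Integer seed or `NULL`.
#' @return A `trace_spec` list.
#' @seealso [make_trace()]
#' @export
trace_spec <- function(kind = c("respirometry", "fluorescence", "absorbance"),
                       ..., events = NULL, noise_sd = 0,
                       sampling_interval = 2, duration = 600, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(noise_sd) || noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (!is.finite(sampling_interval) || sampling_interval <= 0)
    stop("`sampling_interval` must be > 0 s")
  if (!is.finite(duration) || duration <= 2 * sampling_interval)
    stop("`duration` must exceed two sampling intervals")
  params <- list(...)
  defaults <- switch(kind,
    respirometry = list(state2_flux = 25, state3_flux = 100,
                        chamber_volume = 2.1, o2_init = 450),
    fluorescence = list(J_H2O2 = 2, calib_slope = 10, chamber_volume = 2.1,
                        baseline_au = 50),
    absorbance = list(activity = 100, background_rate = 0, epsilon = 6.22,
                      pathlength = 1, assay_volume = 2,
                      direction = "decrease", start_value = NULL)
  )
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown parameter(s) for kind '%s': %s", kind,
                 paste(unknown, collapse = ", ")))
  params <- utils::modifyList(defaults, params)
  if (is.null(events)) {
    events <- switch(kind,
      respirometry = data.frame(time = c(60, 360),
                                label = c("homogenate", "ADP"),
                                stringsAsFactors = FALSE),
      fluorescence = data.frame(time = 60, label = "homogenate",
                                stringsAsFactors = FALSE),
      absorbance = data.frame(time = numeric(0), label = character(0),
                              stringsAsFactors = FALSE))
  }
  if (nrow(events) > 1 && any(diff(events$time) <= 0))
    stop("event schedule must be strictly increasing in time")
  if (nrow(events) && (min(events$time) < 0 || max(events$time) > duration))
    stop("event times must lie within [0, duration]")
  structure(
    c(list(kind = kind), params,
      list(events = events, noise_sd = noise_sd,
           sampling_interval = sampling_interval, duration = duration,
           seed = seed)),
    class = "trace_spec"
  )
}

#' Generate a synthetic assay trace
#'
#' Realizes a [trace_spec()] as a [ts_trace()]: the piecewise-linear
#' latent signal plus Gaussian noise, sampled on a regular grid. With
#' `noise_sd = 0` the analysis stages recover the generating rates to
#' floating-point accuracy, which is the basis of the package's
#' roundtrip tests. Identical spec and seed give identical traces.
#'
#' @param spec A [trace_spec()].
#' @return A [ts_trace()] whose metadata records the generating
#'   parameters (`chamber_volume_ml` / `assay_volume_ml`, `synthetic =
#'   TRUE`).
#' @export
make_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  times <- seq(0, spec$duration, by = spec$sampling_interval)
  latent <- switch(spec$kind,
    respirometry = latent_respirometry(spec, times),
    fluorescence = latent_fluorescence(spec, times),
    absorbance = latent_absorbance(spec, times))
  values <- with_seed(spec$seed, {
    if (spec$noise_sd > 0)
      latent$values + stats::rnorm(length(times), 0, spec$noise_sd)
    else latent$values
  })
  channel <- switch(spec$kind, respirometry = "oxygen_conc",
                    fluorescence = "fluorescence",
                    absorbance = "absorbance")
  ts_trace(times, values, channel = channel, events = spec$events,
           metadata = latent$metadata)
}

# Integrate a piecewise-constant per-second slope with breakpoints.
piecewise_signal <- function(times, start_value, breaks, slopes_per_s) {
  # breaks: k interior breakpoints; slopes: k+1 segment slopes
  vals <- numeric(length(times))
  knots <- c(times[1], breaks)
  level <- start_value
  for (i in seq_along(slopes_per_s)) {
    seg_end <- if (i < length(slopes_per_s)) breaks[i] else Inf
    in_seg <- times >= knots[i] & times <= seg_end
    vals[in_seg] <- level + slopes_per_s[i] * (times[in_seg] - knots[i])
    if (is.finite(seg_end))
      level <- level + slopes_per_s[i] * (seg_end - knots[i])
  }
  vals
}

latent_respirometry <- function(spec, times) {
  v <- spec$chamber_volume
  if (!is.finite(v) || v <= 0) stop("`chamber_volume` must be > 0 mL")
  t_hom <- spec$events$time[spec$events$label == "homogenate"][1]
  t_adp <- spec$events$time[spec$events$label == "ADP"][1]
  if (is.na(t_hom))
    stop("respirometry spec needs a homogenate event")
  # per-second concentration slopes (fluxes are per minute)
  s2 <- -spec$state2_flux / v / 60
  s3 <- -spec$state3_flux / v / 60
  if (is.na(t_adp)) {   # single-state run (e.g. fatty-acid oxidation)
    vals <- piecewise_signal(times, spec$o2_init, t_hom, c(0, s2))
  } else {
    vals <- piecewise_signal(times, spec$o2_init, c(t_hom, t_adp),
                             c(0, s2, s3))
  }
  if (min(vals) < 0)
    stop(sprintf(paste("infeasible spec: oxygen concentration reaches",
                       "%.3g nmol/mL before the trace ends; raise o2_init",
                       "or shorten the trace"), min(vals)))
  list(values = vals,
       metadata = list(chamber_volume_ml = v, synthetic = TRUE,
                       state2_flux = spec$state2_flux,
                       state3_flux = spec$state3_flux))
}

latent_fluorescence <- function(spec, times) {
  v <- spec$chamber_volume
  if (!is.finite(v) || v <= 0) stop("`chamber_volume` must be > 0 mL")
  if (spec$calib_slope <= 0) stop("`calib_slope` must be > 0 AU/uM")
  if (spec$J_H2O2 < 0) stop("`J_H2O2` must be >= 0")
  t_hom <- spec$events$time[spec$events$label == "homogenate"][1]
  if (is.na(t_hom)) t_hom <- 0
  slope_au_s <- (spec$J_H2O2 / v) * spec$calib_slope / 60
  vals <- piecewise_signal(times, spec$baseline_au, t_hom, c(0, slope_au_s))
  list(values = vals,
       metadata = list(chamber_volume_ml = v, synthetic = TRUE,
                       calib_slope = spec$calib_slope,
                       J_H2O2 = spec$J_H2O2))
}

latent_absorbance <- function(spec, times) {
  if (spec$assay_volume <= 0) stop("`assay_volume` must be > 0 mL")
  if (spec$epsilon <= 0) stop("`epsilon` must be > 0")
  total <- spec$activity + spec$background_rate
  # nmol/min -> mM/min -> AU/min -> AU/s
  slope_au_s <- total / (spec$assay_volume * 1000) *
    spec$epsilon * spec$pathlength / 60
  if (spec$direction == "decrease") slope_au_s <- -slope_au_s
  start <- spec$start_value
  if (is.null(start))
    start <- if (spec$direction == "decrease")
      abs(slope_au_s) * spec$duration * 1.5 + 0.5 else 0.05
  vals <- start + slope_au_s * times
  list(values = vals,
       metadata = list(assay_volume_ml = spec$assay_volume,
                       synthetic = TRUE, activity = spec$activity,
                       background_rate = spec$background_rate))
}

#' Generate calibration points for a known calibration line
#'
#' @param slope True calibration slope, AU/uM.
#' @param intercept True blank fluorescence, AU.
#' @param concs H2O2 standards, uM.
#' @param noise_sd Gaussian noise on the responses, AU.
#' @param seed Integer seed or `NULL`.
#' @return Data.frame with columns `conc_uM`, `response_au`.
#' @export
make_calibration_points <- function(slope = 10, intercept = 50,
                                    concs = c(0, 0.5, 1, 2, 4),
                                    noise_sd = 0, seed = NULL) {
  if (slope <= 0) stop("`slope` must be > 0 AU/uM")
  resp <- with_seed(seed, {
    intercept + slope * concs +
      if (noise_sd > 0) stats::rnorm(length(concs), 0, noise_sd) else 0
  })
  data.frame(conc_uM = concs, response_au = resp)
}
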
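#' Fit an Amplex Red H2O2 calibration line
#'
#' The Amplex Red / horseradish peroxidase system converts H2O2 into
#' fluorescent resorufin; known H2O2 additions calibrate the
#' fluorescence response. The line is fitted with an intercept (blank
#' fluorescence exists) but only the slope enters rate conversion.
#'
#' @param conc_uM Known H2O2 concentrations, uM (>= 2 distinct values).
#' @param response_au Fluorescence responses, AU, same length.
#' @return An `h2o2_calibration`: list with `slope` (AU per uM H2O2),
#'   `intercept` (AU), `r_squared`, `n_points`.
#' @export
fit_calibration <- function(conc_uM, response_au) {
  conc_uM <- as.numeric(conc_uM)
  response_au <- as.numeric(response_au)
  if (length(conc_uM) != length(response_au))
    stop("`conc_uM` and `response_au` must have equal length")
  if (length(unique(conc_uM)) < 2)
    stop("calibration needs at least 2 distinct concentrations")
  if (any(!is.finite(conc_uM)) || any(!is.finite(response_au)))
    stop("calibration points must be finite")
  fit <- stats::lm(response_au ~ conc_uM)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop(sprintf("invalid calibration: fitted slope %.4g AU/uM is not positive",
                 slope))
  sst <- sum((response_au - mean(response_au))^2)
  r2 <- if (sst <= 0) NA_real_ else 1 - sum(stats::resid(fit)^2) / sst
  structure(
    list(slope = slope, intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, n_points = length(conc_uM)),
    class = "h2o2_calibration"
  )
}

#' @export
print.h2o2_calibration <- function(x, ...) {
  cat(sprintf(
    "<h2o2_calibration> %.6g AU/uM + %.6g AU (n = %d, r2 = %s)\n",
    x$slope, x$intercept, x$n_points,
    ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared))))
  invisible(x)
}

#' Read calibration points from a two-column CSV
#'
#' @param path CSV with columns `conc_uM` and `response_au`.
#' @return An [fit_calibration()] result.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path))
    stop(sprintf("calibration file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("conc_uM", "response_au")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("calibration file %s lacks column(s): %s",
                 path, paste(missing_cols, collapse = ", ")))
  fit_calibration(df$conc_uM, df$response_au)
}

#' Calibrated H2O2 production rate
#'
#' Converts a fluorescence slope into an H2O2 production rate via the
#' calibration slope: (AU/min) / (AU/uM) = uM/min, and uM = nmol/mL, so
#' multiplying by the chamber volume gives nmol/min.
#'
#' @param fluor_slope Fluorescence slope in AU/min.
#' @param calibration An [fit_calibration()] result.
#' @param chamber_volume Chamber volume in mL (> 0).
#' @return H2O2 production rate in nmol/min.
#' @export
h2o2_rate <- function(fluor_slope, calibration, chamber_volume) {
  stopifnot(inherits(calibration, "h2o2_calibration"))
  if (!is.finite(fluor_slope)) stop("`fluor_slope` must be finite")
  if (!is.finite(calibration$slope) || calibration$slope <= 0)
    stop("calibration slope must be > 0 AU/uM")
  if (!is.finite(chamber_volume) || chamber_volume <= 0)
    stop("`chamber_volume` must be > 0 mL")
  (fluor_slope / calibration$slope) * chamber_volume
}

#' Superoxide production rate from the H2O2 rate
#'
#' Superoxide dismutase in the assay converts superoxide to H2O2 with
#' 2:1 stoichiometry (two superoxide anions dismutate into one H2O2),
#' so the superoxide production rate is exactly twice the measured H2O2
#' rate.
#'
#' @param J_H2O2 H2O2 production rate, nmol/min (>= 0).
#' @return Superoxide production rate, nmol/min: exactly `2 * J_H2O2`.
#' @export
so_rate <- function(J_H2O2) {
  if (!is.finite(J_H2O2) || J_H2O2 < 0)
    stop("`J_H2O2` must be a finite non-negative rate")
  2 * J_H2O2
}

#' Percent electron leak
#'
#' The percentage of electrons fed into the respiratory chain (from
#' NADH or succinate) that are shunted to superoxide rather than
#' delivered to O2 at complex IV. Each superoxide carries one leaked
#' electron; each O2 reduced at complex IV accepts four. With the
#' default `"o2"` denominator convention the leak is expressed relative
#' to the electrons reaching O2:
#' \deqn{100 \times \frac{2\,J_{H_2O_2}}{4\,J_{O_2}}}
#' The `"total"` convention divides by all electrons,
#' `4 J_O2 + 2 J_H2O2`; at the leak magnitudes seen in these assays
#' (about 1–2\%) the two differ by under 0.05 percentage points.
#'
#' @param J_H2O2 H2O2 production rate, nmol/min (>= 0).
#' @param J_O2 Paired oxygen consumption, nmol O2/min (> 0), measured
#'   simultaneously in the same chamber and state segment.
#' @param denominator `"o2"` (default) or `"total"`.
#' @return Percent electron leak (>= 0).
#' @export
percent_electron_leak <- function(J_H2O2, J_O2,
                                  denominator = c("o2", "total")) {
  denominator <- match.arg(denominator)
  if (!is.finite(J_H2O2) || J_H2O2 < 0)
    stop("`J_H2O2` must be a finite non-negative rate")
  if (!is.finite(J_O2) || J_O2 <= 0)
    stop("percent electron leak undefined: `J_O2` must be > 0")
  leaked <- 2 * J_H2O2            # nmol e-/min to superoxide
  to_o2 <- 4 * J_O2               # nmol e-/min to water at complex IV
  denom <- if (denominator == "o2") to_o2 else to_o2 + leaked
  100 * leaked / denom
}

#' Full mitochondrial ROS result for one assay segment
#'
#' Bundles the calibrated H2O2 rate, the 2x superoxide rate, and the
#' percent electron leak against the simultaneously measured oxygen
#' flux. Fluorescence and oxygen slopes are taken over matched windows,
#' as mtROS is recorded simultaneously with respiration.
#'
#' @inheritParams h2o2_rate
#' @param J_O2 Paired oxygen flux, nmol O2/min, or an [oxygen_flux()].
#' @param denominator Leak denominator convention, see
#'   [percent_electron_leak()].
#' @return A `ros_result`: list with `J_H2O2`, `J_SO`, `percent_leak`,
#'   `paired_J_O2`.
#' @export
ros_result <- function(fluor_slope, calibration, chamber_volume, J_O2,
                       denominator = c("o2", "total")) {
  denominator <- match.arg(denominator)
  if (inherits(J_O2, "oxygen_flux")) J_O2 <- J_O2$J_O2
  h <- h2o2_rate(fluor_slope, calibration, chamber_volume)
  if (h < 0)
    stop("negative calibrated H2O2 rate; check trace orientation")
  structure(
    list(J_H2O2 = h, J_SO = so_rate(h),
         percent_leak = percent_electron_leak(h, J_O2, denominator),
         paired_J_O2 = J_O2),
    class = "ros_result"
  )
}

#' @export
print.ros_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<ros_result> J_H2O2 = %.6g nmol/min, J_SO = %.6g nmol/min\n",
    "  percent electron leak = %.4g%% (against J_O2 = %.6g nmol O2/min)\n"),
    x$J_H2O2, x$J_SO, x$percent_leak, x$paired_J_O2))
  invisible(x)
}
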
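#' Estimate a signal slope over a window
#'
#' Ordinary least squares on the raw samples inside a time window,
#' reported per minute (input times are seconds; rates throughout the
#' package are per-minute, so the seconds-to-minutes conversion happens
#' here and nowhere else). No smoothing is applied.
#'
#' Two modes:
#' \describe{
#'   \item{`fixed_window`}{fit over `window` (default: the whole trace).}
#'   \item{`steepest_window`}{scan every contiguous window of length
#'     `window_length` seconds (anchored at sample times, restricted to
#'     `window` when given) and return the one with maximum absolute
#'     slope. Ties are broken by the earliest window start. This mirrors
#'     assays where the fastest initial rate after substrate addition is
#'     the measurand.}
#' }
#'
#' @param trace A [ts_trace()].
#' @param window `NULL` or `c(t_start, t_end)` in seconds.
#' @param mode `"fixed_window"` or `"steepest_window"`.
#' @param window_length Scan-window length in seconds for
#'   `steepest_window` mode (default 30 s).
#' @return A `slope_estimate`: list with `slope` (units/min), `window`
#'   (seconds), `r_squared`, `n`, `mode`.
#' @export
estimate_slope <- function(trace, window = NULL,
                           mode = c("fixed_window", "steepest_window"),
                           window_length = 30) {
  stopifnot(inherits(trace, "ts_trace"))
  mode <- match.arg(mode)
  t <- trace$times
  v <- trace$values
  if (!is.null(window)) {
    if (length(window) != 2 || window[1] >= window[2])
      stop("`window` must be c(t_start, t_end) with t_start < t_end")
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]
    v <- v[keep]
  }
  if (mode == "fixed_window") {
    if (length(t) < 3)
      stop("insufficient data: fewer than 3 samples in the window")
    return(ols_slope(t, v, mode))
  }
  # steepest_window: candidate windows [t_i, t_i + L]
  if (!is.finite(window_length) || window_length <= 0)
    stop("`window_length` must be a positive number of seconds")
  starts <- t[t + window_length <= t[length(t)] + 1e-9]
  best <- NULL
  for (s in starts) {
    keep <- t >= s & t <= s + window_length + 1e-9
    if (sum(keep) < 3) next
    est <- ols_slope(t[keep], v[keep], mode)
    if (is.null(best) || abs(est$slope) > abs(best$slope) + 1e-12)
      best <- est
  }
  if (is.null(best))
    stop("insufficient data: no scan window holds 3 or more samples")
  best
}

# OLS of value on time (seconds); slope reported per minute.
ols_slope <- function(t, v, mode) {
  n <- length(t)
  tc <- t - mean(t)
  vc <- v - mean(v)
  sxx <- sum(tc^2)
  slope_s <- sum(tc * vc) / sxx
  fitted <- mean(v) + slope_s * tc
  sst <- sum(vc^2)
  ssr <- sum((v - fitted)^2)
  r2 <- if (sst <= 0) NA_real_ else max(0, 1 - ssr / sst)
  structure(
    list(slope = slope_s * 60, window = c(t[1], t[n]), r_squared = r2,
         n = n, mode = mode),
    class = "slope_estimate"
  )
}

#' @export
print.slope_estimate <- function(x, ...) {
  cat(sprintf(
    "<slope_estimate> %.6g units/min over [%g, %g] s (n = %d, r2 = %s, %s)\n",
    x$slope, x$window[1], x$window[2], x$n,
    ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared)), x$mode))
  invisible(x)
}
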
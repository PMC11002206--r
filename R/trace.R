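#' Assay time-series traces
#'
#' A `ts_trace` holds one instrument channel sampled over time — oxygen
#' concentration (nmol/mL) from a respirometer chamber, Amplex Red
#' fluorescence (AU), or absorbance (AU) from a spectrophotometer —
#' together with the injection events (homogenate, ADP, substrate,
#' inhibitor, calibrant) that structure the assay and free-form metadata
#' (chamber volume, pathlength, tissue mass, ...).
#'
#' @param times Numeric vector of sample times in seconds, strictly
#'   increasing, length >= 2.
#' @param values Numeric vector of channel values, same length as `times`,
#'   all finite.
#' @param channel One of `"oxygen_conc"`, `"fluorescence"`, `"absorbance"`.
#' @param events `NULL`, or a data.frame with columns `time` (seconds,
#'   within the trace span), `label` (see [event_labels()]) and optionally
#'   `note`.
#' @param metadata Named list of free-form metadata (e.g.
#'   `chamber_volume_ml`, `pathlength_cm`, `tissue_grams`).
#'
#' @return An object of class `ts_trace`.
#' @seealso [read_trace()], [estimate_slope()]
#' @export
ts_trace <- function(times, values,
                     channel = c("oxygen_conc", "fluorescence", "absorbance"),
                     events = NULL, metadata = list()) {
  channel <- match.arg(channel)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("`times` and `values` must have equal length")
  if (length(times) < 2)
    stop("a trace needs at least 2 samples")
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("`times` and `values` must be finite")
  bad <- which(diff(times) <= 0)
  if (length(bad))
    stop(sprintf("times must be strictly increasing; violation at row %d",
                 bad[1] + 1L))
  events <- validate_events(events, range(times))
  if (!is.list(metadata)) stop("`metadata` must be a list")
  structure(
    list(channel = channel, times = times, values = values,
         events = events, metadata = metadata),
    class = "ts_trace"
  )
}

#' Controlled vocabulary for injection-event labels
#' @return Character vector of the accepted event labels.
#' @export
event_labels <- function() {
  c("homogenate", "ADP", "substrate", "inhibitor", "calibrant", "other")
}

validate_events <- function(events, span) {
  if (is.null(events) || (is.data.frame(events) && nrow(events) == 0)) {
    return(data.frame(time = numeric(0), label = character(0),
                      note = character(0), stringsAsFactors = FALSE))
  }
  if (!is.data.frame(events) || !all(c("time", "label") %in% names(events)))
    stop("`events` must be a data.frame with columns `time` and `label`")
  events$time <- as.numeric(events$time)
  events$label <- as.character(events$label)
  if (is.null(events$note)) events$note <- ""
  if (any(!is.finite(events$time)))
    stop("event times must be finite")
  unknown <- setdiff(events$label, event_labels())
  if (length(unknown))
    stop(sprintf("unknown event label(s): %s (valid: %s)",
                 paste(unknown, collapse = ", "),
                 paste(event_labels(), collapse = ", ")))
  out_of_span <- events$time < span[1] | events$time > span[2]
  if (any(out_of_span))
    stop(sprintf("event at t=%g s lies outside the trace span [%g, %g]",
                 events$time[which(out_of_span)[1]], span[1], span[2]))
  events <- events[order(events$time), c("time", "label", "note")]
  rownames(events) <- NULL
  events
}

#' Locate an injection event by label
#'
#' @param trace A [ts_trace()].
#' @param label An event label (see [event_labels()]).
#' @param required If `TRUE` (default), error when absent.
#' @return The event time in seconds (first match), or `NA_real_` when
#'   absent and `required = FALSE`.
#' @export
event_time <- function(trace, label, required = TRUE) {
  stopifnot(inherits(trace, "ts_trace"))
  hit <- trace$events$time[trace$events$label == label]
  if (!length(hit)) {
    if (required)
      stop(sprintf("trace has no '%s' injection event", label),
           call. = FALSE)
    return(NA_real_)
  }
  hit[1]
}

#' @export
print.ts_trace <- function(x, ...) {
  cat(sprintf("<ts_trace> %s: %d samples, t = [%g, %g] s\n",
              x$channel, length(x$times), min(x$times), max(x$times)))
  if (nrow(x$events)) {
    cat("  events:\n")
    for (i in seq_len(nrow(x$events)))
      cat(sprintf("    %8.1f s  %s\n", x$events$time[i], x$events$label[i]))
  }
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' Default trace-CSV dialect
#'
#' Traces are exchanged as delimited text with a header row and one row
#' per sample; an optional event column carries the injection label on
#' the row at which the injection occurred (empty otherwise).
#'
#' @param delim Field delimiter.
#' @param time_col,value_col,event_col Column names for time (seconds),
#'   channel value, and (optional) event label. Set `event_col = NULL`
#'   for files without an event column.
#' @return A list describing the dialect.
#' @export
trace_dialect <- function(delim = ",", time_col = "time_s",
                          value_col = "value", event_col = "event") {
  list(delim = delim, time_col = time_col, value_col = value_col,
       event_col = event_col)
}

#' Read a trace from delimited text
#'
#' @param path Path to the file.
#' @param channel Channel kind, as in [ts_trace()].
#' @param dialect A [trace_dialect()] naming the columns.
#' @param metadata Metadata list attached to the trace.
#' @return A validated [ts_trace()]. Rows with a non-empty event cell
#'   become injection events at that row's time.
#' @export
read_trace <- function(path, channel = "oxygen_conc",
                       dialect = trace_dialect(), metadata = list()) {
  if (!file.exists(path))
    stop(sprintf("trace file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = dialect$delim,
                          stringsAsFactors = FALSE, na.strings = "")
  need <- c(dialect$time_col, dialect$value_col)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("trace file %s lacks required column(s): %s",
                 path, paste(missing_cols, collapse = ", ")))
  events <- NULL
  ec <- dialect$event_col
  if (!is.null(ec) && ec %in% names(df)) {
    lab <- df[[ec]]
    has <- !is.na(lab) & nzchar(trimws(as.character(lab)))
    if (any(has)) {
      events <- data.frame(time = as.numeric(df[[dialect$time_col]][has]),
                           label = trimws(as.character(lab[has])),
                           stringsAsFactors = FALSE)
    }
  }
  ts_trace(df[[dialect$time_col]], df[[dialect$value_col]],
           channel = channel, events = events, metadata = metadata)
}

#' Write a trace as delimited text
#'
#' Inverse of [read_trace()] under the same dialect.
#'
#' @inheritParams read_trace
#' @param trace A [ts_trace()].
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, dialect = trace_dialect()) {
  stopifnot(inherits(trace, "ts_trace"))
  ev <- rep("", length(trace$times))
  if (nrow(trace$events)) {
    for (i in seq_len(nrow(trace$events))) {
      j <- which.min(abs(trace$times - trace$events$time[i]))
      ev[j] <- trace$events$label[i]
    }
  }
  df <- data.frame(trace$times, trace$values, ev, stringsAsFactors = FALSE)
  names(df) <- c(dialect$time_col, dialect$value_col,
                 if (is.null(dialect$event_col)) "event" else dialect$event_col)
  utils::write.table(df, path, sep = dialect$delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @export
plot.ts_trace <- function(x, ...) {
  ylab <- switch(x$channel,
                 oxygen_conc = "O2 concentration (nmol/mL)",
                 fluorescence = "fluorescence (AU)",
                 absorbance = "absorbance (AU)")
  graphics::plot(x$times, x$values, type = "l", xlab = "time (s)",
                 ylab = ylab, ...)
  if (nrow(x$events)) {
    graphics::abline(v = x$events$time, lty = 2, col = "grey40")
    graphics::mtext(x$events$label, side = 3, at = x$events$time,
                    cex = 0.7, line = 0.1)
  }
  invisible(x)
}
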
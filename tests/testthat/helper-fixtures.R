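# Small in-code fixtures shared across test files.

# A trace following an exact line v(t) = intercept + slope_per_s * t.
line_trace <- function(slope_per_s, intercept = 100, times = seq(0, 600, 2),
                       channel = "oxygen_conc", events = NULL,
                       metadata = list()) {
  ts_trace(times, intercept + slope_per_s * times, channel = channel,
           events = events, metadata = metadata)
}

# Write a trace CSV in the default dialect and return its path.
write_temp_trace_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

cs_config <- function(assay_volume = 0.25, pathlength = 1) {
  assay_config("citrate_synthase", epsilon = 13.6, wavelength = 412,
               pathlength = pathlength, assay_volume = assay_volume,
               carrier = "DTNB_thiolate", direction = "increase")
}

resp_events <- function(t_hom = 60, t_adp = 360) {
  data.frame(time = c(t_hom, t_adp), label = c("homogenate", "ADP"),
             stringsAsFactors = FALSE)
}
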
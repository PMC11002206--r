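#' Default pipeline configuration
#'
#' Returns the full configuration the pipeline runs from, as a nested
#' list (serializable to YAML). Top-level sections: `seed`,
#' `output_dir`, `simulate` (synthetic-cohort generation), `inputs`
#' (pre-existing trace/cohort files; used when `simulate$enabled` is
#' false), `dialect` (trace CSV columns), `analysis` (window and
#' convention options) and `assays` (per-enzyme optical constants).
#'
#' @param seed Integer seed.
#' @param output_dir Where result CSVs and the run log are written.
#' @return A config list.
#' @export
default_config <- function(seed = 1, output_dir = "mitoflux_results") {
  list(
    seed = seed,
    output_dir = output_dir,
    simulate = list(
      enabled = TRUE,
      n_per_group = 8,
      cv = 0.15,
      treatments = "none",
      traces = FALSE,
      trace_noise_sd = 0.5
    ),
    inputs = list(
      trace_dir = NULL,
      manifest = NULL,
      cohort_csv = NULL,
      observations_csv = NULL,
      calibration_csv = NULL
    ),
    dialect = list(delim = ",", time_col = "time_s", value_col = "value",
                   event_col = "event"),
    analysis = list(
      leak_denominator = "o2",
      settle_time = 60,
      state_window = 120,
      steepest_window = 30,
      chamber_volume = 2.1,
      posthoc = "tukey"
    ),
    assays = list(
      complex_I = list(epsilon = 6.22, wavelength = 340, pathlength = 1,
                       assay_volume = 2, carrier = "NADH",
                       direction = "decrease"),
      complex_II = list(epsilon = 19.1, wavelength = 600, pathlength = 1,
                        assay_volume = 0.2, carrier = "DCPIP",
                        direction = "decrease"),
      complex_III = list(epsilon = 18.7, wavelength = 550, pathlength = 1,
                         assay_volume = 0.2, carrier = "cytochrome_c",
                         direction = "increase"),
      citrate_synthase = list(epsilon = 13.6, wavelength = 412,
                              pathlength = 1, assay_volume = 0.25,
                              carrier = "DTNB_thiolate",
                              direction = "increase")
    )
  )
}

load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  utils::modifyList(default_config(), config)
}

#' Validate a pipeline configuration
#'
#' Checks the whole configuration and reports every violation at once
#' rather than stopping at the first. The config is validated as given
#' — omitted required fields are violations, not silently filled from
#' the defaults.
#'
#' @param config A config list, or a path to a YAML config file.
#' @return Data.frame with columns `field` and `message`; zero rows
#'   means the config is valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  cfg <- config
  v <- list()
  flag <- function(field, message)
    v[[length(v) + 1]] <<- data.frame(field = field, message = message,
                                      stringsAsFactors = FALSE)
  num_ok <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x)

  if (!num_ok(cfg$seed) || cfg$seed != round(cfg$seed))
    flag("seed", "must be a single integer")
  if (!is.character(cfg$output_dir) || !nzchar(cfg$output_dir))
    flag("output_dir", "must be a non-empty path")

  sim <- cfg$simulate
  if (!isTRUE(sim$enabled) && !isFALSE(sim$enabled))
    flag("simulate.enabled", "must be TRUE or FALSE")
  if (!num_ok(sim$n_per_group) || sim$n_per_group < 1)
    flag("simulate.n_per_group", "must be >= 1")
  if (!num_ok(sim$cv) || sim$cv < 0)
    flag("simulate.cv", "must be >= 0")
  bad_tr <- setdiff(sim$treatments,
                    c("none", "MT_treatment", "MT_prophylaxis"))
  if (length(bad_tr))
    flag("simulate.treatments",
         sprintf("unknown treatment(s): %s", paste(bad_tr, collapse = ", ")))

  if (isFALSE(sim$enabled)) {
    if (is.null(cfg$inputs$cohort_csv))
      flag("inputs.cohort_csv",
           "required when simulate.enabled is false")
    for (f in c("trace_dir", "manifest", "cohort_csv", "observations_csv",
                "calibration_csv")) {
      p <- cfg$inputs[[f]]
      if (!is.null(p) && !file.exists(p))
        flag(paste0("inputs.", f), sprintf("path does not exist: %s", p))
    }
  }

  for (f in c("time_col", "value_col"))
    if (!is.character(cfg$dialect[[f]]) || !nzchar(cfg$dialect[[f]]))
      flag(paste0("dialect.", f), "must be a non-empty column name")

  an <- cfg$analysis
  if (!an$leak_denominator %in% c("o2", "total"))
    flag("analysis.leak_denominator", "must be 'o2' or 'total'")
  for (f in c("settle_time", "state_window", "steepest_window",
              "chamber_volume")) {
    if (!num_ok(an[[f]]) || an[[f]] <= 0)
      flag(paste0("analysis.", f), "must be a positive number")
  }
  if (!an$posthoc %in% c("tukey", "pairwise_t", "none"))
    flag("analysis.posthoc", "must be 'tukey', 'pairwise_t' or 'none'")

  for (enz in c("complex_I", "complex_II", "complex_III",
                "citrate_synthase")) {
    blk <- cfg$assays[[enz]]
    if (is.null(blk)) {
      flag(paste0("assays.", enz), "assay block missing")
      next
    }
    for (f in c("epsilon", "pathlength", "assay_volume")) {
      if (!num_ok(blk[[f]]) || blk[[f]] <= 0)
        flag(paste0("assays.", enz, ".", f), "must be a positive number")
    }
    if (!is.null(blk$direction) &&
        !blk$direction %in% c("decrease", "increase"))
      flag(paste0("assays.", enz, ".direction"),
           "must be 'decrease' or 'increase'")
  }

  if (!length(v))
    return(data.frame(field = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, v)
}
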
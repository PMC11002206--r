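#' Synthetic daily body-weight trajectory
#'
#' Emulates the weight course of indomethacin colitis: diseased animals
#' dip to a sex-specific nadir (default 8\% loss in males, 11\% in
#' females) at days 2-3 and recover to the control growth curve by day
#' 7; controls drift upward. Noise is multiplicative lognormal with the
#' given coefficient of variation (body weights are positive).
#'
#' @param sex `"male"` or `"female"`.
#' @param group `"control"` or `"IBD"`.
#' @param baseline Day-0 body weight, g (> 0).
#' @param days Integer days to generate (default 0:30).
#' @param nadir Fractional weight loss at the disease peak; defaults to
#'   0.08 (male) / 0.11 (female).
#' @param growth_per_day Control growth as a fraction of baseline per
#'   day (default 0.004).
#' @param cv Day-to-day multiplicative noise CV (default 0).
#' @param seed Integer seed or `NULL`.
#' @return Data.frame with columns `day`, `weight_g`.
#' @export
make_weight_trajectory <- function(sex = c("male", "female"),
                                   group = c("control", "IBD"),
                                   baseline = 250, days = 0:30,
                                   nadir = NULL, growth_per_day = 0.004,
                                   cv = 0, seed = NULL) {
  sex <- match.arg(sex)
  group <- match.arg(group)
  if (!is.finite(baseline) || baseline <= 0) stop("`baseline` must be > 0 g")
  if (cv < 0) stop("`cv` must be >= 0")
  if (is.null(nadir)) nadir <- if (sex == "male") 0.08 else 0.11
  control_frac <- 1 + growth_per_day * days
  if (group == "control") {
    frac <- control_frac
  } else {
    frac <- vapply(seq_along(days), function(i) {
      d <- days[i]
      if (d <= 0) 1
      else if (d < 2) 1 + (d / 2) * ((1 - nadir) - 1)
      else if (d <= 3) 1 - nadir
      else if (d < 7) {
        end <- 1 + growth_per_day * 7
        (1 - nadir) + (d - 3) / 4 * (end - (1 - nadir))
      } else control_frac[i]
    }, 1.0)
  }
  w <- baseline * frac
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    w <- with_seed(seed,
                   w * stats::rlnorm(length(w), -sdlog^2 / 2, sdlog))
    # day 0 is the baseline by definition
    w[days == 0] <- baseline
  }
  data.frame(day = days, weight_g = w)
}

#' Default endpoint means for the synthetic cohort
#'
#' Baseline (control female) endpoint values the generator scales by
#' group multipliers. Units: respiration and complex activities in
#' nmol e-/nmol citrate (citrate-synthase-normalized), leak in percent,
#' citrate synthase in nmol/min/g, catalase in U/mL, cardiolipin in
#' nmol/mg, colon length in cm, colon weight in g. Magnitudes are
#' plausible for colon homogenate assays; group contrasts, not absolute
#' levels, are what the cohort emulates.
#'
#' @return Named numeric vector of endpoint means.
#' @export
default_endpoint_means <- function() {
  c(resp_ci = 1.0, resp_cii = 0.8, resp_lcfa = 0.4, resp_mcfa = 0.5,
    rcr = 4, leak_ci = 1.0, leak_cii = 1.2, leak_lcfa = 0.8,
    leak_mcfa = 0.9, complex_I = 2.0, complex_II = 1.5, complex_III = 4.0,
    complex_IV = 6.0, cs_activity = 500, cardiolipin = 15, catalase = 20,
    colon_length = 15, colon_weight = 1.5)
}

#' Default group-effect multipliers for the synthetic cohort
#'
#' Phenomenological encoding of the study's sex-by-treatment effect
#' structure, composed multiplicatively per endpoint:
#' \itemize{
#'   \item control males sit below control females on complex I/II
#'     driven respiration, MCFA oxidation, and complex II-IV activities;
#'   \item IBD males lose citrate synthase, cardiolipin and catalase
#'     activity and double their electron leak (1.4x on MCFA);
#'   \item IBD females halve intact respiration and RCR (4 to 2), lose
#'     complex I and IV activity, double leak on every substrate, and
#'     show colon shortening with hypertrophy;
#'   \item mitoTEMPO arms partially restore female (but not male) IBD
#'     endpoints.
#' }
#'
#' @return A data.frame of rules with columns `sex`, `disease`,
#'   `treatment` (`"*"` = any), `endpoint`, `mult`.
#' @export
default_cohort_effects <- function() {
  rule <- function(sex, disease, treatment, endpoint, mult)
    data.frame(sex = sex, disease = disease, treatment = treatment,
               endpoint = endpoint, mult = mult, stringsAsFactors = FALSE)
  rbind(
    # control-male deficit relative to females
    rule("male", "*", "*", c("resp_ci", "resp_cii", "resp_mcfa"), 0.70),
    rule("male", "*", "*", c("complex_II", "complex_III", "complex_IV"), 0.75),
    # male IBD: content and antioxidant losses, leak increase
    rule("male", "IBD", "*", "cs_activity", 0.60),
    rule("male", "IBD", "*", "cardiolipin", 0.70),
    rule("male", "IBD", "*", "catalase", 0.65),
    rule("male", "IBD", "*", c("leak_ci", "leak_cii", "leak_lcfa"), 2.0),
    rule("male", "IBD", "*", "leak_mcfa", 1.4),
    rule("male", "IBD", "*", "colon_length", 0.85),
    # female IBD: respiration/RCR collapse, CI+CIV loss, leak doubling
    rule("female", "IBD", "*",
         c("resp_ci", "resp_cii", "resp_lcfa", "resp_mcfa", "rcr"), 0.50),
    rule("female", "IBD", "*", c("complex_I", "complex_IV"), 0.60),
    rule("female", "IBD", "*",
         c("leak_ci", "leak_cii", "leak_lcfa", "leak_mcfa"), 2.0),
    rule("female", "IBD", "*", "colon_length", 0.85),
    rule("female", "IBD", "*", "colon_weight", 1.30),
    # mitoTEMPO partially restores female IBD endpoints
    rule("female", "IBD", "MT_treatment",
         c("resp_ci", "resp_cii", "resp_lcfa", "resp_mcfa", "rcr"), 1.60),
    rule("female", "IBD", "MT_treatment", c("complex_I", "complex_IV"), 1.50),
    rule("female", "IBD", "MT_treatment",
         c("leak_ci", "leak_cii", "leak_lcfa", "leak_mcfa"), 0.65),
    rule("female", "IBD", "MT_prophylaxis",
         c("resp_ci", "resp_cii", "resp_lcfa", "resp_mcfa", "rcr"), 1.70),
    rule("female", "IBD", "MT_prophylaxis", c("complex_I", "complex_IV"), 1.50),
    rule("female", "IBD", "MT_prophylaxis",
         c("leak_ci", "leak_cii", "leak_lcfa", "leak_mcfa"), 0.60)
  )
}

match_rules <- function(rules, sex, disease, treatment) {
  hit <- (rules$sex == "*" | rules$sex == sex) &
    (rules$disease == "*" | rules$disease == disease) &
    (rules$treatment == "*" | rules$treatment == treatment)
  rules[hit, , drop = FALSE]
}

group_endpoint_means <- function(sex, disease, treatment, means, effects) {
  out <- means
  hits <- match_rules(effects, sex, disease, treatment)
  for (i in seq_len(nrow(hits))) {
    ep <- hits$endpoint[i]
    if (ep %in% names(out)) out[ep] <- out[ep] * hits$mult[i]
  }
  out
}

#' Specification for a synthetic cohort
#'
#' @param n_per_group Animals per sex-by-disease-by-treatment cell
#'   (>= 1, default 8).
#' @param sexes,diseases,treatments Character vectors defining the
#'   design grid; defaults give the 2x2 sex-by-disease design
#'   (`treatments = c("none", "MT_treatment", "MT_prophylaxis")`
#'   reproduces the mitochondrial-therapy arms; control animals keep
#'   treatment `"none"`).
#' @param cv Between-animal lognormal coefficient of variation
#'   (default 0.15).
#' @param means Baseline endpoint means, see [default_endpoint_means()].
#' @param effects Effect-multiplier rules, see
#'   [default_cohort_effects()].
#' @param baseline_weight Named vector of day-0 body weights (g) per
#'   sex.
#' @param seed Integer seed (default 1).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = 8, sexes = c("male", "female"),
                        diseases = c("control", "IBD"),
                        treatments = "none", cv = 0.15,
                        means = default_endpoint_means(),
                        effects = default_cohort_effects(),
                        baseline_weight = c(male = 250, female = 180),
                        seed = 1) {
  if (!is.finite(n_per_group) || n_per_group < 1)
    stop("`n_per_group` must be >= 1")
  if (cv < 0) stop("`cv` must be >= 0")
  if (!length(sexes) || !length(diseases) || !length(treatments))
    stop("the design grid must have at least one sex, disease and treatment")
  if (any(!names(means) %in% names(default_endpoint_means())) ||
      !length(means))
    stop("`means` must be a named subset of default_endpoint_means()")
  structure(
    list(n_per_group = as.integer(n_per_group), sexes = sexes,
         diseases = diseases, treatments = treatments, cv = cv,
         means = means, effects = effects,
         baseline_weight = baseline_weight, seed = seed),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort
#'
#' Draws per-animal endpoint values as group mean times lognormal noise
#' (mean-preserving: `E[value] = group mean` for every CV), generates
#' daily body-weight trajectories and stool observations whose severity
#' follows the group's disease course, and attaches the design labels.
#' Fully reproducible from the spec's seed.
#'
#' Disease arms that receive mitoTEMPO (`MT_treatment`,
#' `MT_prophylaxis`) show reduced weight-loss nadirs and milder stool
#' categories in females only, matching the endpoint multipliers.
#'
#' @param spec A [cohort_spec()].
#' @param observations Generate the daily weight/stool table
#'   (default `TRUE`; skip for large endpoint-only cohorts).
#' @return A `cohort` list: `animals` (id + design labels + baseline
#'   weight), `endpoints` (one row per animal, one column per
#'   endpoint), `observations` (daily weight and stool rows for days
#'   0-30, or `NULL`), and `spec`.
#' @export
make_cohort <- function(spec = cohort_spec(), observations = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  grid <- expand.grid(sex = spec$sexes, disease = spec$diseases,
                      treatment = spec$treatments,
                      stringsAsFactors = FALSE)
  # therapy arms only exist for diseased animals
  grid <- grid[!(grid$disease == "control" & grid$treatment != "none") |
                 grid$treatment == spec$treatments[1], ]
  grid <- unique(grid)
  with_seed(spec$seed, {
    animals <- list()
    endpoints <- list()
    obs_list <- list()
    idx <- 0
    for (g in seq_len(nrow(grid))) {
      sex <- grid$sex[g]; disease <- grid$disease[g]
      treatment <- grid$treatment[g]
      gmeans <- group_endpoint_means(sex, disease, treatment,
                                     spec$means, spec$effects)
      for (k in seq_len(spec$n_per_group)) {
        idx <- idx + 1
        id <- sprintf("A%03d", idx)
        vals <- lognormal_around(gmeans, spec$cv)
        baseline <- unname(spec$baseline_weight[sex])
        if (is.na(baseline)) baseline <- 250
        animals[[idx]] <- data.frame(
          animal_id = id, sex = sex, disease = disease,
          treatment = treatment,
          group = paste(sex, disease, treatment, sep = "_"),
          baseline_weight_g = baseline, stringsAsFactors = FALSE)
        endpoints[[idx]] <- data.frame(
          animal_id = id, sex = sex, disease = disease,
          treatment = treatment,
          group = paste(sex, disease, treatment, sep = "_"),
          as.list(vals), stringsAsFactors = FALSE)
        if (observations)
          obs_list[[idx]] <- animal_observations(
            id, sex, disease, treatment, baseline, spec$cv)
      }
    }
    structure(
      list(animals = do.call(rbind, animals),
           endpoints = do.call(rbind, endpoints),
           observations = if (observations) do.call(rbind, obs_list),
           spec = spec),
      class = "cohort"
    )
  })
}

# mean-preserving lognormal: E[X] = mean for any cv
lognormal_around <- function(means, cv) {
  if (cv == 0) return(means)
  sdlog <- sqrt(log(1 + cv^2))
  means * stats::rlnorm(length(means), -sdlog^2 / 2, sdlog)
}

# severity 0-3 drives both the weight nadir scaling and stool categories
group_severity <- function(sex, disease, treatment) {
  if (disease != "IBD") return(0)
  base <- if (sex == "female") 3 else 2
  if (sex == "female" && treatment == "MT_treatment") base <- 2
  if (sex == "female" && treatment == "MT_prophylaxis") base <- 1
  base
}

animal_observations <- function(id, sex, disease, treatment, baseline, cv) {
  severity <- group_severity(sex, disease, treatment)
  nadir <- NULL
  if (disease == "IBD" && sex == "female") {
    nadir <- switch(treatment, MT_treatment = 0.11 * 0.7,
                    MT_prophylaxis = 0.11 * 0.5, 0.11)
  }
  traj <- make_weight_trajectory(
    sex, if (disease == "IBD") "IBD" else "control", baseline,
    nadir = nadir, cv = min(cv, 0.02), seed = NULL)
  cons_levels <- stool_categories()$consistency
  col_levels <- stool_categories()$color
  sev_day <- vapply(traj$day, function(d) {
    if (severity == 0) return(0)
    if (d >= 2 && d <= 3) severity
    else if (d %in% c(1, 4, 5)) ceiling(severity / 2)
    else 0
  }, 1.0)
  data.frame(animal_id = id, day = traj$day, body_weight_g = traj$weight_g,
             stool_consistency = cons_levels[sev_day + 1],
             stool_color = col_levels[sev_day + 1],
             stringsAsFactors = FALSE)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d animals in %d groups (seed %s, CV %.2g)\n",
              nrow(x$animals), length(unique(x$animals$group)),
              format(x$spec$seed), x$spec$cv))
  print(table(x$animals$group))
  invisible(x)
}

#' Write per-animal assay traces for a cohort
#'
#' Emits, for each animal, a paired noiseless-plus-noise respirometry
#' trace and fluorescence trace whose generating parameters are derived
#' from the animal's endpoint values (state-3 flux from `resp_ci`, the
#' state-2 flux from its RCR, the H2O2 rate from its complex-I leak),
#' plus a calibration CSV and a manifest tying files to animals. The
#' trace-level quantification stages can then reproduce the endpoint
#' table from raw signals.
#'
#' @param cohort A [make_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param chamber_volume Chamber volume, mL (default 2.1).
#' @param calib_slope Calibration slope, AU/uM (default 10).
#' @param state3_scale Chamber state-3 flux (nmol O2/min) corresponding
#'   to `resp_ci = 1` (default 100).
#' @param noise_sd Gaussian trace noise, signal units (default 0.5).
#' @param seed Integer seed for the trace noise.
#' @return The manifest data.frame (columns `file`, `animal_id`,
#'   `kind`, `chamber_volume_ml`), invisibly; side effect: trace CSVs,
#'   `calibration.csv` and `manifest.csv` under `dir`.
#' @export
write_cohort_traces <- function(cohort, dir, chamber_volume = 2.1,
                                calib_slope = 10, state3_scale = 100,
                                noise_sd = 0.5, seed = 1) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  eps <- cohort$endpoints
  manifest <- list()
  for (i in seq_len(nrow(eps))) {
    id <- eps$animal_id[i]
    state3 <- state3_scale * eps$resp_ci[i]
    state2 <- state3 / eps$rcr[i]
    # leak % = 100 * 2 J_H2O2 / (4 J_O2)  =>  J_H2O2 = leak * 4 J_O2 / 200
    j_h2o2 <- eps$leak_ci[i] * 4 * state3 / 200
    resp_file <- sprintf("%s_resp.csv", id)
    ros_file <- sprintf("%s_ros.csv", id)
    tr <- make_trace(trace_spec("respirometry", state2_flux = state2,
                                state3_flux = state3,
                                chamber_volume = chamber_volume,
                                noise_sd = noise_sd, seed = seed + 2 * i))
    fl <- make_trace(trace_spec("fluorescence", J_H2O2 = j_h2o2,
                                calib_slope = calib_slope,
                                chamber_volume = chamber_volume,
                                events = data.frame(
                                  time = c(60, 360),
                                  label = c("homogenate", "ADP"),
                                  stringsAsFactors = FALSE),
                                noise_sd = noise_sd / 5,
                                seed = seed + 2 * i + 1))
    write_trace(tr, file.path(dir, resp_file))
    write_trace(fl, file.path(dir, ros_file))
    manifest[[length(manifest) + 1]] <- data.frame(
      file = c(resp_file, ros_file), animal_id = id,
      kind = c("respirometry", "fluorescence"),
      chamber_volume_ml = chamber_volume, stringsAsFactors = FALSE)
  }
  calib <- make_calibration_points(slope = calib_slope, noise_sd = 0)
  utils::write.csv(calib, file.path(dir, "calibration.csv"),
                   row.names = FALSE)
  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
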
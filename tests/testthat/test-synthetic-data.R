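test_that("trace generation is deterministic for a given seed", {
  sp <- trace_spec("respirometry", noise_sd = 1, seed = 99)
  t1 <- make_trace(sp)
  t2 <- make_trace(sp)
  expect_identical(t1$values, t2$values)

  t3 <- make_trace(trace_spec("respirometry", noise_sd = 1, seed = 100))
  expect_false(identical(t1$values, t3$values))
})

test_that("generator seeds do not clobber the session RNG state", {
  set.seed(123)
  before <- .Random.seed
  invisible(make_trace(trace_spec("respirometry", noise_sd = 1, seed = 7)))
  expect_identical(.Random.seed, before)
})

test_that("infeasible respirometry specs (oxygen exhausted) are rejected", {
  expect_error(
    make_trace(trace_spec("respirometry", state2_flux = 25,
                          state3_flux = 100, chamber_volume = 2,
                          o2_init = 150)),
    "infeasible")
})

test_that("event schedules must be strictly increasing and in range", {
  expect_error(
    trace_spec("respirometry",
               events = data.frame(time = c(300, 60),
                                   label = c("homogenate", "ADP"))),
    "strictly increasing")
  expect_error(
    trace_spec("respirometry", duration = 200,
               events = data.frame(time = c(60, 360),
                                   label = c("homogenate", "ADP"))),
    "within")
  expect_error(trace_spec("respirometry", bogus = 1), "unknown parameter")
})

test_that("zero-noise roundtrips are exact for every trace kind", {
  # respirometry -> segment_states
  tr <- make_trace(trace_spec("respirometry", state2_flux = 25,
                              state3_flux = 100, chamber_volume = 2.0))
  expect_equal(segment_states(tr, 2.0)$rcr, 4, tolerance = 1e-9)

  # fluorescence -> calibrated H2O2 rate
  fl <- make_trace(trace_spec("fluorescence", J_H2O2 = 2.0,
                              calib_slope = 10, chamber_volume = 2.0))
  cal <- fit_calibration(c(0, 1, 2), c(0, 10, 20))
  sl <- estimate_slope(fl, window = c(120, 400))
  expect_equal(h2o2_rate(sl$slope, cal, 2.0), 2.0, tolerance = 1e-9)

  # absorbance -> Beer-Lambert rate
  ab <- make_trace(trace_spec("absorbance", activity = 120,
                              background_rate = 0, epsilon = 19.1,
                              assay_volume = 0.2, direction = "decrease"))
  cfg <- assay_config("complex_II", epsilon = 19.1, pathlength = 1,
                      assay_volume = 0.2, carrier = "DCPIP",
                      direction = "decrease")
  expect_equal(as.numeric(beer_lambert_rate(estimate_slope(ab)$slope, cfg)),
               120, tolerance = 1e-9)

  # calibration points reproduce the generating line
  pts <- make_calibration_points(slope = 12, intercept = 30)
  fit <- fit_calibration(pts$conc_uM, pts$response_au)
  expect_equal(fit$slope, 12, tolerance = 1e-9)
  expect_equal(fit$intercept, 30, tolerance = 1e-9)
})

test_that("weight trajectories hit the sex-specific nadir and recover", {
  m <- make_weight_trajectory("male", "IBD", baseline = 250)
  dip <- m$weight_g[m$day %in% 2:3] / 250
  expect_equal(dip, c(0.92, 0.92), tolerance = 1e-12)

  f <- make_weight_trajectory("female", "IBD", baseline = 180)
  expect_equal(min(f$weight_g[f$day %in% 2:3]) / 180, 0.89,
               tolerance = 1e-12)

  ctrl <- make_weight_trajectory("male", "control", baseline = 250)
  expect_true(all(ctrl$weight_g >= 250))
  # recovery: by day 7 the diseased animal is back on the control curve
  expect_equal(m$weight_g[m$day >= 7], ctrl$weight_g[ctrl$day >= 7],
               tolerance = 1e-12)
})

test_that("cohort endpoints equal group means at CV 0 and vary by seed", {
  co0 <- make_cohort(cohort_spec(n_per_group = 3, cv = 0, seed = 1))
  fem_ctrl <- co0$endpoints[co0$endpoints$group == "female_control_none", ]
  means <- default_endpoint_means()
  for (ep in names(means))
    expect_equal(fem_ctrl[[ep]], rep(unname(means[ep]), 3))
  # male control deficit applied at CV 0
  male_ctrl <- co0$endpoints[co0$endpoints$group == "male_control_none", ]
  expect_equal(male_ctrl$resp_ci, rep(0.7 * means[["resp_ci"]], 3))
  expect_equal(male_ctrl$rcr, rep(means[["rcr"]], 3))

  co_a <- make_cohort(cohort_spec(n_per_group = 4, seed = 1))
  co_b <- make_cohort(cohort_spec(n_per_group = 4, seed = 2))
  expect_false(identical(co_a$endpoints$rcr, co_b$endpoints$rcr))
  co_a2 <- make_cohort(cohort_spec(n_per_group = 4, seed = 1))
  expect_identical(co_a$endpoints, co_a2$endpoints)
})

test_that("cohort sample means converge to the spec means", {
  co <- make_cohort(cohort_spec(n_per_group = 10000, sexes = "female",
                                diseases = "control", cv = 0.15,
                                seed = 42),
                    observations = FALSE)
  means <- default_endpoint_means()
  for (ep in c("rcr", "cs_activity", "leak_ci", "complex_IV")) {
    rel_err <- abs(mean(co$endpoints[[ep]]) - means[[ep]]) / means[[ep]]
    expect_lt(rel_err, 0.02)
  }
})

test_that("cohort observations encode group severity in stool and weight", {
  co <- make_cohort(cohort_spec(n_per_group = 2, cv = 0, seed = 3))
  obs <- co$observations
  an <- co$animals
  fem_ibd <- an$animal_id[an$group == "female_IBD_none"][1]
  peak <- obs[obs$animal_id == fem_ibd & obs$day == 2, ]
  expect_equal(peak$stool_consistency, "diarrhea")
  expect_equal(peak$stool_color, "bloody")
  ctrl <- an$animal_id[an$group == "male_control_none"][1]
  expect_true(all(obs$stool_consistency[obs$animal_id == ctrl] == "normal"))
})

test_that("written cohort traces quantify back to the endpoint values", {
  co <- make_cohort(cohort_spec(n_per_group = 2, cv = 0.1, seed = 4))
  dir <- file.path(tempdir(), "cohort_traces")
  manifest <- write_cohort_traces(co, dir, noise_sd = 0, seed = 4)
  q <- quantify_traces(dir, manifest,
                       calibration = file.path(dir, "calibration.csv"))
  merged <- merge(co$endpoints, q$endpoints, by = "animal_id")
  expect_equal(merged$rcr_measured, merged$rcr, tolerance = 1e-6)
  expect_equal(merged$percent_leak, merged$leak_ci, tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})
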
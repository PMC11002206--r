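test_that("oxygen flux converts concentration slopes with the sign convention", {
  f <- oxygen_flux(-10, 2.1)
  expect_equal(f$J_O2, 21)
  expect_length(f$qc_flags, 0)

  expect_equal(oxygen_flux(0, 2.1)$J_O2, 0)

  rising <- oxygen_flux(5, 2.0)
  expect_equal(rising$J_O2, -10)
  expect_match(rising$qc_flags, "negative_flux")

  expect_error(oxygen_flux(NA, 2), "finite")
  expect_error(oxygen_flux(-10, 0), "chamber_volume")

  per_g <- oxygen_flux(-10, 2.0, tissue_grams = 0.5)
  expect_equal(per_g$per_gram, 40)
})

test_that("rcr is the state3/state2 ratio and needs positive state 2", {
  expect_equal(rcr(100, 25), 4)
  expect_equal(rcr(60, 30), 2)
  expect_equal(rcr(40, 40), 1)
  expect_error(rcr(100, 0), "RCR undefined")
  expect_error(rcr(100, -5), "RCR undefined")
  # invariance under common rescaling
  expect_equal(rcr(100 * 3.7, 25 * 3.7), rcr(100, 25))
})

test_that("segment_states recovers generating fluxes from noiseless traces", {
  tr <- make_trace(trace_spec("respirometry", state2_flux = 25,
                              state3_flux = 100, chamber_volume = 2.0))
  st <- segment_states(tr, chamber_volume = 2.0)
  expect_equal(st$state2$J_O2, 25, tolerance = 1e-9)
  expect_equal(st$state3$J_O2, 100, tolerance = 1e-9)
  expect_equal(st$rcr, 4, tolerance = 1e-9)

  # identical slopes before and after ADP give RCR 1
  same <- make_trace(trace_spec("respirometry", state2_flux = 40,
                                state3_flux = 40, chamber_volume = 2.0))
  expect_equal(segment_states(same, 2.0)$rcr, 1, tolerance = 1e-9)
})

test_that("segmentation roundtrip holds across flux combinations", {
  for (fluxes in list(c(25, 100), c(30, 60), c(10, 80), c(50, 55))) {
    tr <- make_trace(trace_spec("respirometry", state2_flux = fluxes[1],
                                state3_flux = fluxes[2],
                                chamber_volume = 2.1, o2_init = 600))
    st <- segment_states(tr, 2.1)
    expect_equal(st$state2$J_O2, fluxes[1], tolerance = 1e-9)
    expect_equal(st$state3$J_O2, fluxes[2], tolerance = 1e-9)
    expect_equal(st$rcr, fluxes[2] / fluxes[1], tolerance = 1e-9)
  }
})

test_that("segmentation errors name the missing event", {
  no_adp <- make_trace(trace_spec(
    "respirometry", events = data.frame(time = 60, label = "homogenate")))
  expect_error(segment_states(no_adp, 2.1), "'ADP'")

  t <- seq(0, 600, 2)
  no_hom <- ts_trace(t, 400 - 0.1 * t,
                     events = data.frame(time = 300, label = "ADP"))
  expect_error(segment_states(no_hom, 2.1), "'homogenate'")
})

test_that("a non-consuming state-2 segment raises the RCR-undefined error", {
  t <- seq(0, 600, 2)
  v <- ifelse(t <= 360, 400, 400 - (50 / 60) * (t - 360))  # flat state 2
  tr <- ts_trace(t, v, events = resp_events())
  expect_error(segment_states(tr, 2.1), "RCR undefined")
})

test_that("chamber volume falls back to trace metadata", {
  tr <- make_trace(trace_spec("respirometry", state2_flux = 25,
                              state3_flux = 100, chamber_volume = 2.0))
  st <- segment_states(tr)  # metadata carries chamber_volume_ml
  expect_equal(st$rcr, 4, tolerance = 1e-9)
})

test_that("noisy traces recover fluxes within analytic OLS error", {
  # 200 replicates at fixed seed; each window has m samples at spacing dt,
  # the analytic slope SE is sigma / sqrt(sum((t - tbar)^2)) per second
  set.seed(7)
  sigma <- 1.0
  vol <- 2.1
  n_rep <- 200
  m <- 61                       # samples in a 120 s window at 2 s
  tt <- seq(0, 120, 2)
  se_slope_min <- sigma / sqrt(sum((tt - mean(tt))^2)) * 60  # nmol/mL/min
  se_flux <- se_slope_min * vol
  hits <- 0
  for (r in seq_len(n_rep)) {
    tr <- make_trace(trace_spec("respirometry", state2_flux = 25,
                                state3_flux = 100, chamber_volume = vol,
                                noise_sd = sigma,
                                seed = 1000 + r))
    st <- segment_states(tr, vol)
    hits <- hits +
      (abs(st$state2$J_O2 - 25) < 3 * se_flux) +
      (abs(st$state3$J_O2 - 100) < 3 * se_flux)
  }
  # 3-sigma coverage is 99.7%; allow the binomial tail at 400 draws
  expect_gte(hits / (2 * n_rep), 0.98)
})

test_that("single_state_flux quantifies ADP-free (fatty-acid) runs", {
  tr <- make_trace(trace_spec(
    "respirometry", state2_flux = 30, state3_flux = 30,
    chamber_volume = 2.1,
    events = data.frame(time = 60, label = "homogenate")))
  f <- single_state_flux(tr, 2.1)
  expect_equal(f$J_O2, 30, tolerance = 1e-9)
})
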
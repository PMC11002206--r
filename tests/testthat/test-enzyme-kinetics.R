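configs <- suppressWarnings(default_assay_configs())

test_that("Beer-Lambert conversion matches hand-computed rates", {
  # CI: 0.622/6.22 = 0.1 mM/min x 2 mL x 1000 = 200 nmol NADH/min
  expect_equal(as.numeric(beer_lambert_rate(-0.622, configs$complex_I)),
               200, tolerance = 1e-12)
  # CII: 0.191/19.1 = 0.01 mM/min x 0.2 mL x 1000 = 2 nmol DCPIP/min
  expect_equal(as.numeric(beer_lambert_rate(-0.191, configs$complex_II)),
               2, tolerance = 1e-12)
  expect_equal(as.numeric(beer_lambert_rate(0, configs$complex_I)), 0)
})

test_that("Beer-Lambert rate is linear in slope and volume, inverse in epsilon", {
  r1 <- as.numeric(beer_lambert_rate(-0.1, configs$complex_I))
  expect_equal(as.numeric(beer_lambert_rate(-0.2, configs$complex_I)),
               2 * r1, tolerance = 1e-12)
  cfg2 <- assay_config("complex_I", epsilon = 6.22, pathlength = 1,
                       assay_volume = 4, carrier = "NADH",
                       direction = "decrease")
  expect_equal(as.numeric(beer_lambert_rate(-0.1, cfg2)), 2 * r1,
               tolerance = 1e-12)
  cfg3 <- assay_config("complex_I", epsilon = 3.11, pathlength = 1,
                       assay_volume = 2, carrier = "NADH",
                       direction = "decrease")
  expect_equal(as.numeric(beer_lambert_rate(-0.1, cfg3)), 2 * r1,
               tolerance = 1e-12)
})

test_that("a slope opposing the configured direction is flagged", {
  r <- beer_lambert_rate(+0.1, configs$complex_I)  # NADH should fall
  expect_lt(as.numeric(r), 0)
  expect_match(attr(r, "qc_flags"), "direction_mismatch")
  ok <- beer_lambert_rate(-0.1, configs$complex_I)
  expect_length(attr(ok, "qc_flags"), 0)
})

test_that("background subtraction nets rates and flags over-subtraction", {
  expect_equal(as.numeric(subtract_background(200, 20)), 180)
  expect_equal(as.numeric(subtract_background(50, 50)), 0)
  over <- subtract_background(10, 15)
  expect_equal(as.numeric(over), -5)
  expect_match(attr(over, "qc_flags"), "negative_net_rate")

  a <- structure(10, enzyme = "complex_I")
  b <- structure(2, enzyme = "complex_II")
  expect_error(subtract_background(a, b), "disagree")
})

test_that("citrate synthase activity normalizes to grams of tissue", {
  cfg <- cs_config()
  # +0.136 AU/min: 0.01 mM/min x 0.25 mL = 2.5 nmol/min / 0.005 g = 500
  tr <- line_trace(0.136 / 60, 0.05, seq(0, 180, 2), channel = "absorbance")
  cs <- citrate_synthase_activity(tr, cfg, 0.005)
  expect_equal(cs$rate, 500, tolerance = 1e-9)

  tr2 <- line_trace(0.272 / 60, 0.05, seq(0, 180, 2), channel = "absorbance")
  expect_equal(citrate_synthase_activity(tr2, cfg, 0.005)$rate, 1000,
               tolerance = 1e-9)

  flat <- line_trace(0, 0.05, seq(0, 180, 2), channel = "absorbance")
  expect_equal(citrate_synthase_activity(flat, cfg, 0.005)$rate, 0)

  expect_error(citrate_synthase_activity(tr, cfg, 0), "> 0 g")
  # falling DTNB absorbance is physically wrong: flagged, not clipped
  inv <- line_trace(-0.136 / 60, 0.5, seq(0, 180, 2), channel = "absorbance")
  res <- citrate_synthase_activity(inv, cfg, 0.005)
  expect_lt(res$rate, 0)
  expect_true(any(grepl("negative_cs_rate", res$qc_flags)))
})

test_that("electron equivalence table drives flux conversion", {
  expect_equal(to_electron_flux(100, "NADH"), 200)
  expect_equal(to_electron_flux(50, "cytochrome_c"), 50)
  expect_equal(to_electron_flux(21, "O2"), 84)
  expect_equal(to_electron_flux(10, "DCPIP"), 20)
  expect_error(to_electron_flux(10, "ubiquinol"), "no electron equivalence")
})

test_that("complex IV is quantified as oxygen consumption with 4 e-/O2", {
  tr <- make_trace(trace_spec(
    "respirometry", state2_flux = 21, state3_flux = 21,
    chamber_volume = 2.0,
    events = data.frame(time = 60, label = "homogenate")))
  act <- complex_iv_activity(tr, 2.0)
  expect_equal(act$rate_substrate, 21, tolerance = 1e-9)
  expect_equal(act$electron_flux, 84, tolerance = 1e-9)

  tr2 <- make_trace(trace_spec(
    "respirometry", state2_flux = 12.5, state3_flux = 12.5,
    chamber_volume = 2.0,
    events = data.frame(time = 60, label = "homogenate")))
  act2 <- complex_iv_activity(tr2, 2.0)
  expect_equal(act2$rate_substrate, 12.5, tolerance = 1e-9)
  expect_equal(act2$electron_flux, 50, tolerance = 1e-9)

  no_event <- line_trace(-0.05, 400, seq(0, 300, 2))
  expect_error(complex_iv_activity(no_event, 2.0), "homogenate")
})

test_that("normalization to citrate synthase cancels per-minute units", {
  expect_equal(normalize_to_cs(500, 500), 1)
  expect_equal(normalize_to_cs(200, 50), 4)
  expect_error(normalize_to_cs(200, 0), "undefined")
  # content-normalization invariance
  for (c in c(0.5, 2, 10))
    expect_equal(normalize_to_cs(200 * c, 50 * c), 4, tolerance = 1e-12)
})

test_that("absorbance traces roundtrip through slope, Beer-Lambert and background", {
  activity <- 150
  bg <- 20
  total_tr <- make_trace(trace_spec("absorbance", activity = activity,
                                    background_rate = bg, epsilon = 6.22,
                                    assay_volume = 2,
                                    direction = "decrease"))
  bg_tr <- make_trace(trace_spec("absorbance", activity = 0,
                                 background_rate = bg, epsilon = 6.22,
                                 assay_volume = 2, direction = "decrease"))
  cfg <- configs$complex_I
  total_rate <- beer_lambert_rate(estimate_slope(total_tr)$slope, cfg)
  bg_rate <- beer_lambert_rate(estimate_slope(bg_tr)$slope, cfg)
  net <- subtract_background(total_rate, bg_rate)
  expect_equal(as.numeric(net), activity, tolerance = 1e-9)
})

test_that("quantify_enzyme composes the whole chain with per-gram output", {
  activity <- 150
  bg <- 20
  total_tr <- make_trace(trace_spec("absorbance", activity = activity,
                                    background_rate = bg, epsilon = 6.22,
                                    assay_volume = 2,
                                    direction = "decrease"))
  bg_tr <- make_trace(trace_spec("absorbance", activity = 0,
                                 background_rate = bg, epsilon = 6.22,
                                 assay_volume = 2, direction = "decrease"))
  act <- quantify_enzyme(total_tr, configs$complex_I,
                         background_trace = bg_tr, tissue_grams = 0.01)
  expect_equal(act$rate_substrate, activity, tolerance = 1e-6)
  expect_equal(act$electron_flux, 2 * activity, tolerance = 1e-6)
  expect_equal(act$rate_per_gram, activity / 0.01, tolerance = 1e-6)
  expect_true(act$background_subtracted)

  no_bg <- quantify_enzyme(total_tr, configs$complex_I)
  expect_false(no_bg$background_subtracted)
  expect_true(any(grepl("no_background_trace", no_bg$qc_flags)))
})
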
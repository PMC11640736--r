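test_that("quasi-adiabatic analysis recovers D = c * dT exactly without noise", {
  tr <- generate_calorimeter_trace("quasi_adiabatic", true_dose = 1.412, c = 706)
  d <- analyze_quasi_adiabatic(tr, calorimeter_constants(c = 706))
  expect_lt(abs(as.numeric(d) - 1.412) / 1.412, 1e-9)
  # the generated ramp totals 2.0 mK
  expect_equal(attr(d, "details")$delta_t_mk, 2.0, tolerance = 1e-9)
  # zero dose -> pure drift, zero recovered dose
  tr0 <- generate_calorimeter_trace("quasi_adiabatic", true_dose = 0,
                                    drift_rate = 0.01)
  expect_lt(abs(as.numeric(analyze_quasi_adiabatic(tr0))), 1e-12)
})

test_that("linear drift cancels exactly in the quasi-adiabatic extrapolation", {
  doses <- sapply(c(0, 0.005, -0.02, 0.1), function(dr) {
    tr <- generate_calorimeter_trace("quasi_adiabatic", true_dose = 0.9,
                                     drift_rate = dr)
    as.numeric(analyze_quasi_adiabatic(tr))
  })
  expect_lt(max(abs(doses - 0.9)) / 0.9, 1e-9)
})

test_that("isothermal analysis integrates the power depression to the dose", {
  # baseline 10 mW, 1 Gy into 1 g over 60 s: mean depression 1/60 mW
  tr <- generate_calorimeter_trace("isothermal", true_dose = 1, mass = 1e-3,
                                   baseline_power = 10,
                                   irradiation = c(120, 180))
  d <- analyze_isothermal(tr, calorimeter_constants(mass = 1e-3))
  expect_lt(abs(as.numeric(d) - 1) , 1e-9)
  win <- tr$time > 120 & tr$time < 180
  expect_equal(mean(10 - tr$signal[win]), 1 / 60, tolerance = 0.01)
  # zero depression -> 0 Gy
  tr0 <- generate_calorimeter_trace("isothermal", true_dose = 0)
  expect_lt(abs(as.numeric(analyze_isothermal(tr0))), 1e-12)
})

test_that("SOBP energy-layer steps round-trip through both analyses", {
  steps <- data.frame(time = c(120, 132, 144, 156, 168),
                      intensity = c(1, 0.85, 0.7, 0.55, 0.4))
  for (mode in c("quasi_adiabatic", "isothermal")) {
    tr <- generate_calorimeter_trace(mode, true_dose = 1.7, c = 706,
                                     mass = 7.4e-4, irradiation = c(120, 180),
                                     layer_steps = steps)
    d <- if (mode == "quasi_adiabatic") {
      analyze_quasi_adiabatic(tr)
    } else {
      analyze_isothermal(tr)
    }
    expect_lt(abs(as.numeric(d) - 1.7) / 1.7, 1e-6)
  }
})

test_that("analysis windows are validated", {
  tr <- generate_calorimeter_trace("quasi_adiabatic", true_dose = 1)
  expect_error(analyze_quasi_adiabatic(tr, pre_window = c(100, 130)),
               "overlaps")
  expect_error(analyze_quasi_adiabatic(tr, post_window = c(170, 240)),
               "overlaps")
  expect_error(analyze_quasi_adiabatic(tr, pre_window = c(118, 119.6)),
               ">= 10")
  expect_error(analyze_isothermal(tr), "not in isothermal mode")
})

test_that("integration is insensitive to the sampling rate", {
  for (dt in c(0.5, 0.05)) {
    tr <- generate_calorimeter_trace("isothermal", true_dose = 1.3,
                                     mass = 1e-3, dt = dt)
    expect_lt(abs(as.numeric(analyze_isothermal(tr, calorimeter_constants(mass = 1e-3))) - 1.3) / 1.3,
              1e-6)
  }
})

test_that("noisy traces recover the dose without bias and noise sets the spread", {
  truth <- 1.5
  n <- 60
  rec <- sapply(seq_len(n), function(s) {
    tr <- generate_calorimeter_trace("quasi_adiabatic", true_dose = truth,
                                     noise_sd = 0.01, seed = s)
    as.numeric(analyze_quasi_adiabatic(tr))
  })
  se <- sd(rec) / sqrt(n)
  expect_lt(abs(mean(rec) - truth), 3 * se)
  rec_quiet <- sapply(seq_len(20), function(s) {
    tr <- generate_calorimeter_trace("quasi_adiabatic", true_dose = truth,
                                     noise_sd = 0.002, seed = 1000 + s)
    as.numeric(analyze_quasi_adiabatic(tr))
  })
  expect_lt(sd(rec_quiet), sd(rec))
})

test_that("combining modes averages the doses and flags disagreement", {
  expect_equal(combine_modes(1, 1)$dose, 1)
  cm <- combine_modes(1.00, 1.02, flag_threshold = 0.05)
  expect_equal(cm$dose, 1.01)
  expect_equal(cm$consistency, 0.01)
  expect_false(cm$flagged)
  expect_warning(cm2 <- combine_modes(1.00, 1.02), "disagree")
  expect_true(cm2$flagged)
})

test_that("the two-mode mean beats either single mode over repeated runs", {
  truth <- 2
  n <- 100
  err <- sapply(seq_len(n), function(s) {
    qa <- analyze_quasi_adiabatic(generate_calorimeter_trace(
      "quasi_adiabatic", true_dose = truth, noise_sd = 0.008, seed = s
    ))
    iso <- analyze_isothermal(generate_calorimeter_trace(
      "isothermal", true_dose = truth, mass = 7.4e-4, noise_sd = 0.0004,
      seed = 10000 + s
    ))
    comb <- (as.numeric(qa) + as.numeric(iso)) / 2
    c(qa = as.numeric(qa) - truth, iso = as.numeric(iso) - truth,
      comb = comb - truth)
  })
  rmse <- sqrt(rowMeans(err^2))
  expect_lt(rmse["comb"], rmse["qa"])
  expect_lt(rmse["comb"], rmse["iso"])
})

test_that("traces round-trip through CSV with sidecars", {
  tr <- generate_calorimeter_trace("isothermal", true_dose = 1, mass = 1e-3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_calorimeter_trace(tr, f)
  back <- read_calorimeter_trace(f)
  expect_equal(back$signal, tr$signal, tolerance = 1e-12)
  expect_identical(attr(back, "mode"), "isothermal")
  d <- analyze_isothermal(back, calorimeter_constants(mass = 1e-3))
  expect_lt(abs(as.numeric(d) - 1), 1e-9)
})
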
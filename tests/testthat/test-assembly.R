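test_that("expanded uncertainties convert to standard by halving", {
  expect_equal(expanded_to_standard(0.96), 0.48)
  expect_equal(expanded_to_standard(0), 0)
  u <- 0.123
  expect_equal(expanded_to_standard(2 * u), u)
  expect_error(expanded_to_standard(-1), ">= 0")
})

test_that("dose-to-water is the product of the core dose and all factors", {
  unit <- list(
    correction_factor("kimp", 1), correction_factor("kgap", 1),
    correction_factor("dose_conversion", 1)
  )
  expect_equal(dose_to_water(1, unit, config = "mono")$Dw, 1)

  sobp <- list(
    correction_factor("dose_conversion", 1.1428),
    correction_factor("kimp", 1.0012),
    correction_factor("kgap", 0.9984),
    correction_factor("kvert_pspc", 0.9766)
  )
  r <- dose_to_water(1, sobp, config = "sobp")
  expect_equal(r$Dw, 1.1428 * 1.0012 * 0.9984 * 0.9766, tolerance = 1e-12)
  expect_equal(round(r$Dw, 4), 1.1156)

  # commutativity: any factor ordering gives the identical product
  r2 <- dose_to_water(1, rev(sobp), config = "sobp")
  expect_identical(r2$Dw, r$Dw)

  # multiplicativity in the core dose
  r3 <- dose_to_water(2.5, sobp, config = "sobp")
  expect_identical(r3$Dw, 2.5 * r$Dw / 1)
})

test_that("factor bookkeeping rejects duplicates, gaps and strays", {
  base <- list(
    correction_factor("kimp", 1.0013), correction_factor("kgap", 1.0002),
    correction_factor("dose_conversion", 1.1164)
  )
  expect_error(dose_to_water(1, base[1:2], config = "mono"),
               "missing correction factors: dose_conversion")
  expect_error(dose_to_water(1, c(base, base[1]), config = "mono"),
               "duplicate correction factors: kimp")
  expect_error(dose_to_water(1, c(base, list(correction_factor("kvert_pspc", 0.98))),
                             config = "mono"),
               "unexpected")
  # chamber-style assembly via explicit required names
  ch <- dose_to_water(1, c(base, list(correction_factor("kvert_roos", 0.964))),
                      required = c("kimp", "kgap", "dose_conversion", "kvert_roos"))
  expect_equal(ch$Dw, 1.0013 * 1.0002 * 1.1164 * 0.964, tolerance = 1e-12)
})

test_that("the uncertainty budget combines in quadrature and recomputes from its table", {
  fs <- list(
    correction_factor("kimp", 1.0013, type_a = 0.06, type_b = 0.08),
    correction_factor("kgap", 1.0002, type_a = 0.06, type_b = 0.11),
    correction_factor("dose_conversion", 1.1164, type_a = 0.05, type_b = 0.48)
  )
  r <- dose_to_water(1, fs, config = "mono", d_core_type_a = 0.2, d_core_type_b = 0.1)
  want <- sqrt(0.2^2 + 0.1^2 + 0.06^2 + 0.08^2 + 0.06^2 + 0.11^2 + 0.05^2 + 0.48^2)
  expect_equal(r$combined_pct, want, tolerance = 1e-12)
  expect_identical(r$expanded_pct, 2 * r$combined_pct)
  expect_identical(budget_combined(r$components), r$combined_pct)

  # serialization round-trips bit-exactly
  f <- withr::local_tempfile(fileext = ".yaml")
  write_dose_result(r, f)
  back <- read_dose_result(f)
  expect_identical(back$Dw, r$Dw)
  expect_identical(back$components$value, r$components$value)
  expect_identical(budget_combined(back$components), back$combined_pct)
})

test_that("tidy and glance expose the budget and the headline numbers", {
  fs <- list(
    correction_factor("kimp", 1.0013, type_a = 0.06),
    correction_factor("kgap", 1.0002), correction_factor("dose_conversion", 1.1164)
  )
  r <- dose_to_water(1.2, fs, config = "mono")
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$name, c("d_core", "kimp", "kgap", "dose_conversion"))
  g <- glance(r)
  expect_equal(g$Dw, r$Dw)
  expect_equal(g$n_components, 4L)
})

test_that("ratio report divides the two branches and harmonizes footprints", {
  fs <- list(
    correction_factor("kimp", 1), correction_factor("kgap", 1),
    correction_factor("dose_conversion", 1)
  )
  a <- dose_to_water(1.05, fs, config = "mono")
  b <- dose_to_water(1.00, fs, config = "mono")
  rr <- ratio_report(a, b, correction_factor("kprof", 1))
  expect_equal(rr$ratio, 1.05)
  expect_equal(ratio_report(a, a, correction_factor("kprof", 1))$ratio, 1)
  # kprof rescales the chamber reading
  rr2 <- ratio_report(a, b, correction_factor("kprof", 0.9949, type_b = 0.51))
  expect_equal(rr2$ratio, 1.05 / 0.9949, tolerance = 1e-12)
  a2 <- dose_to_water(1.05, fs, config = "mono", d_core_type_a = 0.3)
  rr3 <- ratio_report(a2, b, correction_factor("kprof", 1, type_b = 0.4))
  expect_equal(rr3$u_pct, sqrt(0.3^2 + 0.4^2), tolerance = 1e-12)
})

test_that("an end-to-end synthetic run is consistent with unity within its uncertainty", {
  # same true dose into the calorimeter branch (two noisy trace analyses)
  # and the chamber branch (noisy reading); the ratio should cover 1 within
  # its expanded (k = 2) uncertainty in ~95% of runs
  truth <- 2
  unitf <- list(
    correction_factor("kimp", 1), correction_factor("kgap", 1),
    correction_factor("dose_conversion", 1)
  )
  n_runs <- 24
  pilot <- sapply(seq_len(12), function(s) {
    qa <- analyze_quasi_adiabatic(generate_calorimeter_trace(
      "quasi_adiabatic", true_dose = truth, noise_sd = 0.01, seed = 5000 + s
    ))
    iso <- analyze_isothermal(generate_calorimeter_trace(
      "isothermal", true_dose = truth, mass = 7.4e-4, noise_sd = 0.001,
      seed = 6000 + s
    ))
    (as.numeric(qa) + as.numeric(iso)) / 2
  })
  core_u_pct <- 100 * sd(pilot) / truth # empirical sd of repeated analyses
  chamber_u_pct <- 0.3

  covered <- sapply(seq_len(n_runs), function(s) {
    qa <- analyze_quasi_adiabatic(generate_calorimeter_trace(
      "quasi_adiabatic", true_dose = truth, noise_sd = 0.01, seed = s
    ))
    iso <- analyze_isothermal(generate_calorimeter_trace(
      "isothermal", true_dose = truth, mass = 7.4e-4, noise_sd = 0.001,
      seed = 7000 + s
    ))
    d_core <- (as.numeric(qa) + as.numeric(iso)) / 2
    cal <- dose_to_water(d_core, unitf, config = "mono",
                         d_core_type_a = core_u_pct)
    set.seed(8000 + s)
    chamber <- dose_to_water(truth * (1 + rnorm(1, 0, chamber_u_pct / 100)),
                             unitf, config = "mono",
                             d_core_type_a = chamber_u_pct)
    rr <- ratio_report(cal, chamber)
    abs(rr$ratio - 1) <= rr$expanded_pct / 100
  })
  expect_gte(sum(covered), round(0.8 * n_runs))
})
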
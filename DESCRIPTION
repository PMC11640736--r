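Package: minibeamdose
Title: Dosimetry Analysis for Proton Minibeam Fields with a Graphite Calorimeter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for primary-standard graphite calorimetry in
    spatially fractionated (minibeam) proton fields. Provides a synthetic
    generator for planar minibeam dose maps, Bragg and spread-out-Bragg-peak
    depth-dose curves and calorimeter signal traces; radiochromic film
    processing (scan averaging, net optical density, calibration fitting);
    dose-area-product-per-unit-area statistics over circular detector
    apertures and their offset scans; Gaussian detector-positioning Type B
    uncertainty propagation; the multiplicative correction factors of the
    dose-to-water equation (impurity, gap, vertical-position, profile and
    r80-scaled dose conversion); quasi-adiabatic and isothermal calorimeter
    trace analysis; and assembly of dose-to-water with a quadrature
    uncertainty budget.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
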
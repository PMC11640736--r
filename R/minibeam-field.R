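#' Specification of a planar minibeam field
#'
#' Describes a spatially fractionated proton field produced by a multi-slit
#' collimator: a row of parallel beamlet stripes (slits) with Gaussian
#' lateral broadening at the measurement depth, a uniform scatter background
#' in the valleys, a linear dose non-uniformity along the beamlets, and an
#' optional per-slit amplitude ramp mimicking a collimator tilt.
#'
#' Defaults correspond to a 15-slit collimator with 400 um slits at 4 mm
#' center-to-center pitch, 5 cm slit length, inside a 7.2 x 7.2 cm field.
#' `blur_sigma` sets the beamlet half-width growth from proton scatter with
#' depth: 0.9 mm emulates a shallow (2 cm water-equivalent) measurement in a
#' mono-energetic beam where beamlets are sharply distinct; 1.3 mm emulates
#' the middle of a spread-out Bragg peak at 10 cm water-equivalent depth
#' where they remain distinct but less so.
#'
#' @param n_slits Number of slits (>= 1).
#' @param slit_width Slit width in mm; must be smaller than `pitch`.
#' @param pitch Center-to-center slit separation, mm.
#' @param slit_length Slit length (vertical beamlet extent), mm.
#' @param field_extent Length-2 numeric, horizontal and vertical field size
#'   in mm; the slit array must fit inside the horizontal extent.
#' @param blur_sigma Gaussian lateral broadening sigma of each beamlet at
#'   the measurement depth, mm (> 0).
#' @param valley_fraction Uniform scatter background as a fraction of the
#'   beamlet peak, in \[0, 1).
#' @param vertical_gradient Fractional dose change per mm along the slit
#'   direction (positive y = upward). The default +0.0033/mm makes the dose
#'   11 mm below center ~3.6% lower than at center, calibrating the
#'   surrogate so the vertical-position correction there has the magnitude
#'   seen on measured films (~0.964); it is a tunable surrogate parameter,
#'   not a measured value.
#' @param tilt_asymmetry Per-slit amplitude ramp across the field
#'   (outermost slits scaled by 1 +/- `tilt_asymmetry`), mimicking a small
#'   collimator tilt; 0 disables it.
#' @param peak_dose Dose at a beamlet peak, Gy.
#' @param noise_sd Per-pixel Gaussian noise sigma, Gy (0 = noiseless).
#'
#' @return A `minibeam_field_spec` list.
#' @export
#'
#' @examples
#' spec <- minibeam_field_spec(noise_sd = 0)
#' map <- generate_minibeam_map(spec, pixel_spacing = 0.2, seed = 1)
#' map
minibeam_field_spec <- function(n_slits = 15,
                                slit_width = 0.4,
                                pitch = 4.0,
                                slit_length = 50.0,
                                field_extent = c(72, 72),
                                blur_sigma = 0.9,
                                valley_fraction = 0.05,
                                vertical_gradient = 0.0033,
                                tilt_asymmetry = 0,
                                peak_dose = 5,
                                noise_sd = 0) {
  if (length(field_extent) == 1L) field_extent <- rep(field_extent, 2L)
  spec <- list(
    n_slits = n_slits, slit_width = slit_width, pitch = pitch,
    slit_length = slit_length, field_extent = as.numeric(field_extent),
    blur_sigma = blur_sigma, valley_fraction = valley_fraction,
    vertical_gradient = vertical_gradient, tilt_asymmetry = tilt_asymmetry,
    peak_dose = peak_dose, noise_sd = noise_sd
  )
  validate_minibeam_field_spec(spec)
  structure(spec, class = "minibeam_field_spec")
}

validate_minibeam_field_spec <- function(spec) {
  if (spec$n_slits < 1) abort("invalid field spec: n_slits must be >= 1.")
  if (spec$slit_width >= spec$pitch) {
    abort("invalid field spec: slit_width must be smaller than pitch.")
  }
  array_width <- (spec$n_slits - 1) * spec$pitch + spec$slit_width
  if (array_width > spec$field_extent[1]) {
    abort(sprintf(
      "invalid field spec: slit array (%.1f mm) exceeds horizontal field extent (%.1f mm).",
      array_width, spec$field_extent[1]
    ))
  }
  if (spec$blur_sigma <= 0) abort("invalid field spec: blur_sigma must be > 0.")
  if (spec$valley_fraction < 0 || spec$valley_fraction >= 1) {
    abort("invalid field spec: valley_fraction must be in [0, 1).")
  }
  if (spec$peak_dose <= 0) abort("invalid field spec: peak_dose must be > 0.")
  if (spec$noise_sd < 0) abort("invalid field spec: noise_sd must be >= 0.")
  invisible(spec)
}

# slit center x positions, symmetric about 0
minibeam_slit_centers <- function(spec) {
  (seq_len(spec$n_slits) - (spec$n_slits + 1) / 2) * spec$pitch
}

# smooth 0->1 edge over the last 2 mm; d = signed distance inside the edge
cosine_edge <- function(d) {
  ifelse(d <= 0, 0, ifelse(d >= 2, 1, 0.5 * (1 - cos(pi * d / 2))))
}

# per-slit amplitude ramp encoding tilt_asymmetry; 1 everywhere when 0
minibeam_slit_ramp <- function(spec) {
  if (spec$n_slits == 1L) return(1)
  i <- seq_len(spec$n_slits)
  1 + spec$tilt_asymmetry * (i - (spec$n_slits + 1) / 2) / ((spec$n_slits - 1) / 2)
}

#' Evaluate the noiseless minibeam generating function
#'
#' The analytic dose model behind [generate_minibeam_map()]:
#' `peak_dose * [v + (1 - v) * sum_i ramp_i G_i(x)] * (1 + g*y) * env(y)`,
#' where `G_i` is the slit top-hat convolved with a Gaussian of
#' `blur_sigma`, normalized to unit peak; `env(y)` is 1 inside the slit
#' length with cosine-smoothed ends over the last 2 mm. Exposed so tests
#' and supersampling oracles can evaluate the exact field at arbitrary
#' points.
#'
#' @param spec A [minibeam_field_spec()].
#' @param x,y Numeric vectors of coordinates (mm, field frame). `x` and `y`
#'   are crossed: the result is a `length(y)` x `length(x)` matrix unless
#'   both have equal length and `grid = FALSE`.
#' @param grid If `TRUE` (default) evaluate on the outer grid `y` x `x`;
#'   if `FALSE`, evaluate point-wise on equal-length vectors.
#' @return Matrix (grid) or vector (point-wise) of dose, Gy.
#' @export
minibeam_dose_function <- function(spec, x, y, grid = TRUE) {
  centers <- minibeam_slit_centers(spec)
  ramp <- minibeam_slit_ramp(spec)
  s <- spec$blur_sigma
  hw <- spec$slit_width / 2
  gnorm <- 2 * pnorm(hw / s) - 1 # unit-peak normalization of top-hat * Gaussian

  profile <- numeric(length(x))
  for (i in seq_along(centers)) {
    profile <- profile + ramp[i] *
      (pnorm((x - centers[i] + hw) / s) - pnorm((x - centers[i] - hw) / s)) / gnorm
  }
  profile <- spec$valley_fraction + (1 - spec$valley_fraction) * profile
  # irradiated-field edge: dose (including the scatter background) falls to
  # zero outside the scanned field width, cosine-smoothed over 2 mm
  dx_edge <- spec$field_extent[1] / 2 - abs(x)
  profile <- profile * cosine_edge(dx_edge)

  d <- spec$slit_length / 2 - abs(y) # distance to slit end
  env <- cosine_edge(d)
  vert <- pmax(0, 1 + spec$vertical_gradient * y) * env

  if (grid) {
    spec$peak_dose * outer(vert, profile)
  } else {
    stopifnot(length(x) == length(y))
    spec$peak_dose * vert * profile
  }
}

#' Generate a synthetic minibeam dose map
#'
#' Rasterizes [minibeam_dose_function()] on a cell-centered grid covering
#' the field extent and adds per-pixel Gaussian noise (clipped at zero
#' dose). Deterministic for a fixed seed; the caller's RNG state is left
#' untouched.
#'
#' @param spec A [minibeam_field_spec()].
#' @param pixel_spacing Grid pitch, mm (default 600 dpi = 25.4/600 mm).
#' @param seed Integer seed for the pixel noise. Required when
#'   `noise_sd > 0`.
#' @param grid_extent Length-2 raster extent, mm; defaults to the field
#'   extent. May be larger (dose is zero beyond the field edges), e.g. so
#'   that apertures wider than the field stay inside the map.
#' @return A [dose_map()].
#' @export
generate_minibeam_map <- function(spec, pixel_spacing = 25.4 / 600, seed = NULL,
                                  grid_extent = spec$field_extent) {
  validate_minibeam_field_spec(spec)
  stop_if_not_scalar_number(pixel_spacing, "pixel_spacing", positive = TRUE)
  if (length(grid_extent) == 1L) grid_extent <- rep(grid_extent, 2L)
  if (any(grid_extent < spec$field_extent)) {
    abort("`grid_extent` must cover the field extent.")
  }
  nx <- ceiling(grid_extent[1] / pixel_spacing)
  ny <- ceiling(grid_extent[2] / pixel_spacing)
  xs <- (seq_len(nx) - (nx + 1) / 2) * pixel_spacing
  ys <- ((ny + 1) / 2 - seq_len(ny)) * pixel_spacing

  values <- minibeam_dose_function(spec, xs, ys, grid = TRUE)
  if (spec$noise_sd > 0) {
    if (is.null(seed)) abort("`seed` is required when noise_sd > 0.")
    noise <- with_seed(seed, matrix(rnorm(nx * ny, sd = spec$noise_sd), ny, nx))
    values <- pmax(values + noise, 0)
  }
  dose_map(values, pixel_spacing = pixel_spacing)
}
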
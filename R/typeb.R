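#' Gaussian detector-positioning model
#'
#' The detector is assumed to be positioned within +/- `conf_halfwidth` mm
#' of the nominal coordinates with 95% confidence, Gaussian per axis:
#' mean at the nominal position, sigma = halfwidth / 2. The default is the
#' +/- 1 mm at 95% model around (0, -11) mm used for a detector mounted
#' 11 mm below the field center.
#'
#' @param mean Length-2 nominal position (x, y), mm.
#' @param sigma Per-axis standard deviation, mm (> 0).
#' @param conf_halfwidth Stated 95% half-width, mm; must be consistent
#'   with `sigma` (2 * sigma).
#' @return A `positioning_model` list.
#' @export
positioning_model <- function(mean = c(0, -11), sigma = 0.5,
                              conf_halfwidth = 2 * sigma) {
  stop_if_not_scalar_number(sigma, "sigma", positive = TRUE)
  if (length(mean) != 2L) abort("`mean` must be a length-2 (x, y) position.")
  if (abs(conf_halfwidth - 2 * sigma) > 1e-9) {
    abort(sprintf(
      "inconsistent positioning model: 2*sigma = %.3g mm but the stated 95%% half-width is %.3g mm.",
      2 * sigma, conf_halfwidth
    ))
  }
  structure(
    list(mean = as.numeric(mean), sigma = sigma,
         conf_halfwidth = conf_halfwidth),
    class = "positioning_model"
  )
}

# draw axis positions from the model, clipped to the scan range
sample_axis_positions <- function(scan, center, sigma, n) {
  rng <- range(scan$offset)
  pos <- rnorm(n, mean = center, sd = sigma)
  n_clipped <- sum(pos < rng[1] | pos > rng[2])
  list(pos = pmin(pmax(pos, rng[1]), rng[2]), n_clipped = n_clipped)
}

#' Type B dose uncertainty from detector positioning
#'
#' Samples detector positions per axis from the Gaussian positioning model,
#' evaluates the (monotone-cubic interpolated) normalized offset-response
#' scans at the sampled positions, and takes the per-axis standard
#' deviation of the sampled relative doses as the Type B standard
#' uncertainty due to positioning on that axis; the two axes are combined
#' in quadrature. Samples falling beyond a scan's measured range are
#' clipped to the range ends and counted.
#'
#' @param scan_h,scan_v Horizontal and vertical `offset_scan`s from
#'   [horizontal_offset_scan()] / [vertical_offset_scan()].
#' @param model A [positioning_model()]; its x mean is used for the
#'   horizontal axis and its y mean for the vertical axis.
#' @param n_samples Number of Gaussian draws per axis (a warning is issued
#'   below 1000).
#' @param seed Integer seed (deterministic result per seed).
#' @return A one-row `type_b_result` tibble: `sd_h_pct`, `sd_v_pct`,
#'   `combined_pct` (= quadrature of the two, exactly), `n_clipped_h`,
#'   `n_clipped_v`, `n_samples`, `seed`.
#' @export
#'
#' @examples
#' spec <- minibeam_field_spec(noise_sd = 0)
#' m <- generate_minibeam_map(spec, pixel_spacing = 0.2)
#' sh <- horizontal_offset_scan(m, radius = 8)
#' sv <- vertical_offset_scan(m, radius = 8)
#' sample_type_b(sh, sv, positioning_model(), n_samples = 1e4, seed = 1)
sample_type_b <- function(scan_h, scan_v, model = positioning_model(),
                          n_samples = 1e6, seed = 1) {
  stopifnot(inherits(model, "positioning_model"))
  if (n_samples < 1000) {
    warn(sprintf("n_samples = %d gives an unstable Type B estimate; use >= 1000.", n_samples))
  }
  for (scan in list(scan_h, scan_v)) {
    ctr <- if (identical(attr(scan, "axis"), "vertical")) model$mean[2] else model$mean[1]
    rng <- range(scan$offset)
    if (ctr - 2 * model$sigma < rng[1] || ctr + 2 * model$sigma > rng[2]) {
      warn(sprintf(
        "%s scan [%g, %g] mm does not cover +/- 2 sigma around %g mm; tail samples will be clipped.",
        attr(scan, "axis"), rng[1], rng[2], ctr
      ))
    }
  }

  fh <- offset_scan_interpolator(scan_h)
  fv <- offset_scan_interpolator(scan_v)
  res <- with_seed(seed, {
    h <- sample_axis_positions(scan_h, model$mean[1], model$sigma, n_samples)
    v <- sample_axis_positions(scan_v, model$mean[2], model$sigma, n_samples)
    list(h = h, v = v, vals_h = fh(h$pos), vals_v = fv(v$pos))
  })
  sd_h <- 100 * sd(res$vals_h)
  sd_v <- 100 * sd(res$vals_v)
  new_tibble(
    list(
      sd_h_pct = sd_h, sd_v_pct = sd_v,
      combined_pct = sqrt(sd_h^2 + sd_v^2),
      n_clipped_h = res$h$n_clipped, n_clipped_v = res$v$n_clipped,
      n_samples = as.integer(n_samples), seed = as.integer(seed)
    ),
    nrow = 1L, class = "type_b_result"
  )
}

#' Combine uncertainty components in quadrature
#'
#' Square root of the sum of squares of standard-uncertainty components
#' (all at the same coverage factor, conventionally k = 1, in fractional
#' percent).
#'
#' @param components Numeric vector of non-negative components, %.
#' @return Combined component, %.
#' @export
#'
#' @examples
#' quadrature(c(0.37, 1.55)) # 1.59
quadrature <- function(components) {
  if (!is.numeric(components) || length(components) < 1L) {
    abort("`components` must be a non-empty numeric vector.")
  }
  if (any(components < 0)) {
    abort("uncertainty components must be >= 0.")
  }
  sqrt(sum(components^2))
}
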
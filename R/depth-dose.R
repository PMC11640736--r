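#' Depth-dose curves
#'
#' A `depth_dose_curve` is a tibble with columns `depth_mm` (strictly
#' increasing) and `dose` (arbitrary scale, >= 0), plus a `medium`
#' attribute (`"water"` or `"graphite"`).
#'
#' @param depth_mm Strictly increasing depths, mm.
#' @param dose Non-negative doses (arbitrary scale).
#' @param medium Medium label, `"water"` or `"graphite"`.
#' @return A `depth_dose_curve` tibble.
#' @export
depth_dose_curve <- function(depth_mm, dose, medium = c("water", "graphite")) {
  medium <- match.arg(medium)
  if (length(depth_mm) != length(dose) || length(dose) < 3L) {
    abort("`depth_mm` and `dose` must be equal-length vectors (>= 3 points).")
  }
  if (any(diff(depth_mm) <= 0)) abort("`depth_mm` must be strictly increasing.")
  if (any(dose < 0)) abort("`dose` must be >= 0.")
  out <- new_tibble(
    list(depth_mm = as.numeric(depth_mm), dose = as.numeric(dose)),
    nrow = length(dose), class = "depth_dose_curve"
  )
  attr(out, "medium") <- medium
  out
}

# Analytic Bragg-like pristine shape: a gently rising entrance channel that
# is smoothly cut off past the peak (protons stop), plus a Gaussian-broadened
# Bragg peak of unit amplitude at `z_peak`. A surrogate exercising the r80
# machinery, not a transport calculation.
bragg_shape <- function(z, z_peak, sigma) {
  entrance <- (0.22 + 0.12 * (pmax(z, 0) / z_peak)^2) *
    0.5 * (1 - tanh((z - z_peak) / (1.2 * sigma)))
  entrance + exp(-(z - z_peak)^2 / (2 * sigma^2))
}

# distal 80% depth of a sampled curve (internal: dense-grid version)
distal_r80 <- function(z, d) {
  imax <- which.max(d)
  thr <- 0.8 * d[imax]
  below <- which(d[imax:length(d)] < thr)
  if (length(below) == 0L) return(NA_real_)
  i2 <- imax + below[1] - 1L
  i1 <- i2 - 1L
  z[i1] + (thr - d[i1]) * (z[i2] - z[i1]) / (d[i2] - d[i1])
}

#' Generate a synthetic depth-dose curve
#'
#' Produces an analytic Bragg-like pristine curve whose distal 80% falloff
#' depth (r80) equals `range_mm`, or a spread-out Bragg peak (SOBP): a
#' non-negative-least-squares weighted sum of shifted pristine curves whose
#' plateau over `[range_mm - sobp_width_mm, range_mm]` is flat to within 1%.
#' The Bragg peak Gaussian width scales with range (~1.2%, emulating range
#' straggling).
#'
#' @param range_mm Target r80 of the pristine curve / distal end of the
#'   SOBP plateau, mm (> 0).
#' @param medium Medium label passed through to the curve.
#' @param sobp_width_mm Modulation width, mm; 0 (default) returns a
#'   pristine curve. Must be < `range_mm`.
#' @param dz Depth grid step, mm.
#' @return A [depth_dose_curve()].
#' @export
#'
#' @examples
#' pdd <- generate_depth_dose(76, "water")
#' find_r80(pdd)
generate_depth_dose <- function(range_mm, medium = c("water", "graphite"),
                                sobp_width_mm = 0, dz = 0.1) {
  medium <- match.arg(medium)
  stop_if_not_scalar_number(range_mm, "range_mm", positive = TRUE)
  stop_if_not_scalar_number(sobp_width_mm, "sobp_width_mm", nonnegative = TRUE)
  stop_if_not_scalar_number(dz, "dz", positive = TRUE)
  if (sobp_width_mm >= range_mm) {
    abort("`sobp_width_mm` must be smaller than `range_mm`.")
  }

  sigma <- 0.012 * range_mm
  z <- seq(0, range_mm + max(8 * sigma, 5), by = dz)

  pristine_at <- function(r80_target) {
    # fixed-point adjustment of the peak position so the sampled distal 80%
    # crossing lands on r80_target (entrance channel shifts it slightly)
    zp <- r80_target - 0.668 * sigma
    for (k in 1:4) {
      d <- bragg_shape(z, zp, sigma)
      zx <- distal_r80(z, d)
      zp <- zp + (r80_target - zx)
    }
    bragg_shape(z, zp, sigma)
  }

  if (sobp_width_mm == 0) {
    dose <- pristine_at(range_mm)
    return(depth_dose_curve(z, dose / max(dose), medium))
  }

  # SOBP: components whose r80s cover the plateau and overshoot its distal
  # end by ~2.5 sigma so flatness holds right up to range_mm
  z_lo <- range_mm - sobp_width_mm
  r80s <- seq(z_lo, range_mm + 2.5 * sigma, by = max(0.8 * sigma, dz))
  comp <- vapply(r80s, pristine_at, numeric(length(z)))
  plateau <- z >= z_lo & z <= range_mm
  w <- pracma::lsqnonneg(comp[plateau, , drop = FALSE], rep(1, sum(plateau)))$x
  dose <- as.vector(comp %*% w)
  depth_dose_curve(z, dose / max(dose), medium)
}

#' Distal r80 of a depth-dose curve
#'
#' Depth on the distal (downstream) side of the dose maximum where the dose
#' first falls to 80% of the maximum, located by linear interpolation
#' between the bracketing samples. Used as the range surrogate for
#' depth-scale matching between media.
#'
#' @param curve A [depth_dose_curve()] (any tibble/data.frame with
#'   `depth_mm` and `dose` columns works).
#' @return r80 in mm.
#' @export
find_r80 <- function(curve) {
  z <- curve$depth_mm
  d <- curve$dose
  if (is.null(z) || is.null(d)) abort("`curve` needs depth_mm and dose columns.")
  r80 <- distal_r80(z, d)
  if (is.na(r80)) abort("curve truncated before r80: no distal 80% crossing.")
  r80
}

#' Read and write depth-dose curves as two-column CSV
#'
#' @param curve A [depth_dose_curve()].
#' @param path CSV path; columns `depth_mm`, `dose`.
#' @return `write_depth_dose()` returns `path` invisibly;
#'   `read_depth_dose()` returns a [depth_dose_curve()].
#' @param medium Medium label for `read_depth_dose()`.
#' @export
write_depth_dose <- function(curve, path) {
  utils::write.csv(
    data.frame(depth_mm = curve$depth_mm, dose = curve$dose),
    path,
    row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_depth_dose
#' @export
read_depth_dose <- function(path, medium = c("water", "graphite")) {
  df <- utils::read.csv(path)
  depth_dose_curve(df$depth_mm, df$dose, match.arg(medium))
}
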
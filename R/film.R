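#' Average repeated film scans
#'
#' Per-pixel arithmetic mean of k repeated scans of the same film piece,
#' the standard way to suppress scanner noise (variance falls as 1/k for
#' independent noise).
#'
#' @param stack A list of numeric matrices of identical shape (k >= 1), or
#'   a single matrix.
#' @return A matrix of per-pixel means.
#' @export
average_scans <- function(stack) {
  if (is.matrix(stack)) stack <- list(stack)
  if (!is.list(stack) || length(stack) < 1L) {
    abort("`stack` must be a non-empty list of matrices.")
  }
  ref <- dim(stack[[1]])
  for (i in seq_along(stack)) {
    if (!is.matrix(stack[[i]]) || !is.numeric(stack[[i]])) {
      abort(sprintf("scan %d is not a numeric matrix.", i))
    }
    if (!identical(dim(stack[[i]]), ref)) {
      abort(sprintf(
        "scan %d has shape %d x %d, expected %d x %d.",
        i, nrow(stack[[i]]), ncol(stack[[i]]), ref[1], ref[2]
      ))
    }
  }
  Reduce(`+`, stack) / length(stack)
}

#' Net optical density of an irradiated film
#'
#' `netOD = log10(unexposed / irradiated)` per pixel, computed from the
#' (averaged) scanner transmission values of the irradiated film and an
#' unexposed film from the same batch.
#'
#' @param irradiated,unexposed Numeric matrices of identical shape with
#'   strictly positive pixel values (scanner transmission).
#' @return Matrix of net optical density.
#' @export
net_optical_density <- function(irradiated, unexposed) {
  if (!identical(dim(irradiated), dim(unexposed))) {
    abort("`irradiated` and `unexposed` must have identical shape.")
  }
  if (any(irradiated <= 0) || any(unexposed <= 0)) {
    abort("pixel values must be strictly positive to take optical density.")
  }
  log10(unexposed / irradiated)
}

#' Fit a film calibration curve
#'
#' Least-squares fit of `dose = a * netOD + b * netOD^n` to calibration
#' points, with `a, b >= 0` and `n` free in \[1, 3\]. The form passes
#' through the origin (zero netOD -> zero dose) and is monotone by
#' construction for non-negative coefficients; monotonicity is nevertheless
#' verified on a dense grid and a non-monotone result is flagged as a
#' calibration failure.
#'
#' @param netOD Net optical densities of the calibration films.
#' @param dose Delivered doses, Gy (non-negative, including 0 Gy).
#' @param n Either `NULL` (default: exponent fitted within \[1, 3\]) or a
#'   fixed exponent.
#' @return A `calibration_curve` list with elements `coef` (a, b, n),
#'   `dose_range`, `netOD_range` and `residual_sd` (Gy).
#' @export
#'
#' @examples
#' od <- seq(0, 0.5, length.out = 8)
#' fit <- fit_calibration(od, 10 * od + 40 * od^2.5)
#' fit$coef
fit_calibration <- function(netOD, dose, n = NULL) {
  if (length(netOD) != length(dose) || length(dose) < 4L) {
    abort("need >= 4 calibration points with matching netOD/dose lengths.")
  }
  if (any(dose < 0)) abort("calibration doses must be non-negative.")
  if (min(dose) > 0) abort("the calibration scale must include 0 Gy.")

  ord <- order(netOD)
  od_s <- netOD[ord]
  dose_s <- dose[ord]
  dup <- duplicated(od_s) & !duplicated(paste(od_s, dose_s))
  if (any(dup)) {
    abort("calibration failure: duplicate netOD values with different doses (non-monotone input).")
  }

  df <- data.frame(od = netOD, dose = dose)
  pos <- df$od > 0
  # linear-model starting values on the positive points
  start_n <- if (is.null(n)) 2 else n
  lmfit <- lm(dose ~ 0 + od + I(od^start_n), data = df[pos, , drop = FALSE])
  a0 <- max(coef(lmfit)[1], 0, na.rm = TRUE)
  b0 <- max(coef(lmfit)[2], 1e-6, na.rm = TRUE)

  if (is.null(n)) {
    # purely linear data cannot identify the exponent (b -> 0 makes the
    # model insensitive to n); fall back to a fixed exponent in that case
    fit <- tryCatch(
      minpack.lm::nlsLM(
        dose ~ a * od + b * od^nn,
        data = df,
        start = list(a = a0, b = b0, nn = start_n),
        lower = c(0, 0, 1), upper = c(Inf, Inf, 3),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(fit_calibration(netOD, dose, n = 2))
    }
    cf <- coef(fit)
    cf <- c(a = unname(cf["a"]), b = unname(cf["b"]), n = unname(cf["nn"]))
  } else {
    fit <- minpack.lm::nlsLM(
      dose ~ a * od + b * od^n,
      data = df,
      start = list(a = a0, b = b0),
      lower = c(0, 0), upper = c(Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    cf <- c(coef(fit), n = n)
  }

  curve <- structure(
    list(
      form = "dose = a*netOD + b*netOD^n",
      coef = cf,
      netOD_range = range(netOD),
      dose_range = range(dose),
      residual_sd = sqrt(mean(stats::residuals(fit)^2))
    ),
    class = "calibration_curve"
  )
  # monotone on a dense grid over the validity range
  grid <- seq(curve$netOD_range[1], curve$netOD_range[2], length.out = 512)
  if (any(diff(predict_calibration(curve, grid)) < -1e-12)) {
    abort("calibration failure: fitted curve is not monotone over the calibration range.")
  }
  curve
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> dose = %.4g*netOD + %.4g*netOD^%.4g; netOD in [%.3g, %.3g]; residual sd %.3g Gy\n",
    x$coef["a"], x$coef["b"], x$coef["n"],
    x$netOD_range[1], x$netOD_range[2], x$residual_sd
  ))
  invisible(x)
}

#' @rdname fit_calibration
#' @param curve A `calibration_curve`.
#' @param x Net optical density values (for `predict_calibration`) or doses
#'   in Gy (for `calibration_inverse`).
#' @export
predict_calibration <- function(curve, x) {
  cf <- unname(curve$coef)
  cf[1] * x + cf[2] * x^cf[3]
}

#' @rdname fit_calibration
#' @export
calibration_inverse <- function(curve, x) {
  # numerical inverse by monotone interpolation of a dense forward table
  grid <- seq(0, curve$netOD_range[2] * 1.05, length.out = 2048)
  fwd <- predict_calibration(curve, grid)
  monotone_interp(fwd, grid)(x)
}

#' @export
#' @method tidy calibration_curve
tidy.calibration_curve <- function(x, ...) {
  tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @export
#' @method glance calibration_curve
glance.calibration_curve <- function(x, ...) {
  tibble(
    residual_sd = x$residual_sd,
    netOD_min = x$netOD_range[1], netOD_max = x$netOD_range[2],
    dose_min = x$dose_range[1], dose_max = x$dose_range[2]
  )
}

#' Convert a netOD map to a calibrated dose map
#'
#' Applies a fitted calibration curve per pixel. netOD values above the
#' calibration range are clipped to the range end with a warning (no
#' extrapolation); the pixel spacing is derived from the scan resolution
#' (25.4/dpi mm).
#'
#' @param netOD Numeric matrix of net optical density.
#' @param curve A `calibration_curve` from [fit_calibration()].
#' @param dpi Scanner resolution, dots per inch (default 600).
#' @param origin Passed to [dose_map()].
#' @return A [dose_map()].
#' @export
apply_calibration <- function(netOD, curve, dpi = 600, origin = c(0, 0)) {
  if (!is.matrix(netOD)) abort("`netOD` must be a matrix.")
  upper <- curve$netOD_range[2]
  n_over <- sum(netOD > upper)
  if (n_over > 0) {
    warn(sprintf(
      "%d pixels above the calibration netOD range (max %.3g) were clipped.",
      n_over, upper
    ))
    netOD <- pmin(netOD, upper)
  }
  dose <- pmax(predict_calibration(curve, pmax(netOD, 0)), 0)
  dose_map(dose, pixel_spacing = 25.4 / dpi, origin = origin)
}
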
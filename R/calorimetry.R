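#' Calorimeter constants
#'
#' @param c Specific heat capacity of the core, J/(kg K).
#' @param mass Core mass, kg.
#' @return A `calorimeter_constants` list.
#' @export
calorimeter_constants <- function(c = 706, mass = 7.4e-4) {
  stop_if_not_scalar_number(c, "c", positive = TRUE)
  stop_if_not_scalar_number(mass, "mass", positive = TRUE)
  structure(list(c = c, mass = mass), class = "calorimeter_constants")
}

# validate and extract an analysis window; default: `margin` seconds
# directly before (pre) / after (post) the irradiation window
resolve_window <- function(trace, window, side, margin = 60) {
  irr <- attr(trace, "irradiation")
  if (is.null(irr)) abort("trace has no irradiation window attribute.")
  if (is.null(window)) {
    window <- if (side == "pre") c(irr[1] - margin, irr[1]) else c(irr[2], irr[2] + margin)
  }
  if (length(window) != 2L || window[2] <= window[1]) {
    abort("analysis windows must be [t0, t1] with t1 > t0.")
  }
  if (side == "pre" && window[2] > irr[1] + 1e-9) {
    abort("pre-irradiation window overlaps the irradiation window.")
  }
  if (side == "post" && window[1] < irr[2] - 1e-9) {
    abort("post-irradiation window overlaps the irradiation window.")
  }
  sel <- trace$time >= window[1] - 1e-9 & trace$time <= window[2] + 1e-9
  # the exact boundary samples of the irradiation window belong to the
  # irradiation, not to the drifts
  sel <- sel & if (side == "pre") trace$time < irr[1] - 1e-9 else trace$time > irr[2] + 1e-9
  if (sum(sel) < 10L) {
    abort(sprintf("%s-irradiation window contains %d samples; >= 10 required.",
                  side, sum(sel)))
  }
  sel
}

# linear drift fit over selected samples
drift_fit <- function(trace, sel) {
  fit <- lm(signal ~ time, data = data.frame(time = trace$time[sel],
                                             signal = trace$signal[sel]))
  list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    residual_sd = sqrt(mean(stats::residuals(fit)^2))
  )
}

#' Dose from a quasi-adiabatic calorimeter trace
#'
#' Fits straight drift lines to the pre- and post-irradiation windows,
#' extrapolates both to the irradiation midpoint, and takes the
#' radiation-induced temperature rise as the difference of the two
#' extrapolated lines there (this cancels any common linear drift). The
#' core dose is the temperature rise times the specific heat capacity.
#'
#' @param trace A `calorimeter_trace` in quasi-adiabatic mode (signal mK).
#' @param consts A [calorimeter_constants()].
#' @param pre_window,post_window Length-2 `[t0, t1]` in s, strictly before
#'   / after the irradiation window, each covering >= 10 samples; `NULL`
#'   uses the 60 s adjacent to the window.
#' @param residual_sd_max Drift-fit residual threshold (signal units)
#'   above which a warning is issued.
#' @return Core dose, Gy (scalar), with a `"details"` attribute carrying
#'   the drift fits and the temperature rise in mK.
#' @export
analyze_quasi_adiabatic <- function(trace, consts = calorimeter_constants(),
                                    pre_window = NULL, post_window = NULL,
                                    residual_sd_max = Inf) {
  if (!identical(attr(trace, "mode"), "quasi_adiabatic")) {
    abort("trace is not in quasi-adiabatic mode.")
  }
  sel_pre <- resolve_window(trace, pre_window, "pre")
  sel_post <- resolve_window(trace, post_window, "post")
  pre <- drift_fit(trace, sel_pre)
  post <- drift_fit(trace, sel_post)
  if (max(pre$residual_sd, post$residual_sd) > residual_sd_max) {
    warn(sprintf("drift-fit residual sd %.3g exceeds threshold %.3g.",
                 max(pre$residual_sd, post$residual_sd), residual_sd_max))
  }
  irr <- attr(trace, "irradiation")
  t_mid <- mean(irr)
  delta_t_mk <- (post$intercept + post$slope * t_mid) -
    (pre$intercept + pre$slope * t_mid)
  if (delta_t_mk < 0 && abs(delta_t_mk) > 6 * max(pre$residual_sd, post$residual_sd, 1e-12)) {
    abort("negative radiation-induced temperature rise beyond noise; check windows/trace.")
  }
  dose <- consts$c * delta_t_mk / 1000
  attr(dose, "details") <- list(pre = pre, post = post,
                                delta_t_mk = delta_t_mk, t_mid = t_mid)
  dose
}

#' Dose from an active-isothermal calorimeter trace
#'
#' Fits a single straight baseline across the pre- and post-irradiation
#' windows, integrates the depression of the electrical heating power
#' below that baseline over the irradiation window (trapezoidal rule),
#' and divides the integrated energy by the core mass.
#'
#' @inheritParams analyze_quasi_adiabatic
#' @return Core dose, Gy (scalar), with a `"details"` attribute.
#' @export
analyze_isothermal <- function(trace, consts = calorimeter_constants(),
                               pre_window = NULL, post_window = NULL,
                               residual_sd_max = Inf) {
  if (!identical(attr(trace, "mode"), "isothermal")) {
    abort("trace is not in isothermal mode.")
  }
  sel_pre <- resolve_window(trace, pre_window, "pre")
  sel_post <- resolve_window(trace, post_window, "post")
  base <- drift_fit(trace, sel_pre | sel_post)
  if (base$residual_sd > residual_sd_max) {
    warn(sprintf("baseline residual sd %.3g exceeds threshold %.3g.",
                 base$residual_sd, residual_sd_max))
  }
  irr <- attr(trace, "irradiation")
  in_win <- trace$time >= irr[1] - 1e-9 & trace$time <= irr[2] + 1e-9
  tw <- trace$time[in_win]
  depression <- (base$intercept + base$slope * tw) - trace$signal[in_win]
  energy_mj <- pracma::trapz(tw, depression) # mW * s = mJ
  dose <- energy_mj / 1000 / consts$mass
  attr(dose, "details") <- list(baseline = base, energy_mj = energy_mj)
  dose
}

#' Combine the two calorimeter operating modes
#'
#' Arithmetic mean of the quasi-adiabatic and isothermal dose estimates,
#' with the half-difference reported as a mode-consistency metric. A
#' relative disagreement above `flag_threshold` sets a warning flag in the
#' output.
#'
#' @param dose_qa,dose_iso Doses from the two modes, Gy (> 0).
#' @param flag_threshold Relative disagreement that sets the flag
#'   (default 1%).
#' @return One-row tibble: `dose` (Gy), `consistency` (half-difference,
#'   Gy), `relative_difference`, `flagged`.
#' @export
#'
#' @examples
#' combine_modes(1.00, 1.02)
combine_modes <- function(dose_qa, dose_iso, flag_threshold = 0.01) {
  stop_if_not_scalar_number(as.numeric(dose_qa), "dose_qa", positive = TRUE)
  stop_if_not_scalar_number(as.numeric(dose_iso), "dose_iso", positive = TRUE)
  dose_qa <- as.numeric(dose_qa)
  dose_iso <- as.numeric(dose_iso)
  m <- mean(c(dose_qa, dose_iso))
  rel <- abs(dose_qa - dose_iso) / m
  flagged <- rel > flag_threshold
  if (flagged) {
    warn(sprintf("quasi-adiabatic and isothermal doses disagree by %.2f%%.",
                 100 * rel))
  }
  tibble(
    dose = m,
    consistency = abs(dose_qa - dose_iso) / 2,
    relative_difference = rel,
    flagged = flagged
  )
}
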
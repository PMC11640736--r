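#' Correction factors
#'
#' A `correction_factor` is a one-row tibble naming a multiplicative factor
#' of the dose-to-water equation together with its Type A and Type B
#' standard uncertainties (k = 1, fractional percent).
#'
#' @param name Factor name, one of `kvert_roos`, `kvert_pspc`, `kprof`,
#'   `kimp`, `kgap`, `dose_conversion`, or `d_core` (the measured core dose
#'   entry of the budget).
#' @param value Factor value (> 0), dimensionless.
#' @param type_a,type_b Standard uncertainties at k = 1, %.
#' @param note Free-text provenance note.
#' @return A one-row `correction_factor` tibble.
#' @export
correction_factor <- function(name, value, type_a = 0, type_b = 0, note = "") {
  if (!is.character(name) || length(name) != 1L) abort("`name` must be a string.")
  stop_if_not_scalar_number(value, "value", positive = TRUE)
  stop_if_not_scalar_number(type_a, "type_a", nonnegative = TRUE)
  stop_if_not_scalar_number(type_b, "type_b", nonnegative = TRUE)
  new_tibble(
    list(name = name, value = value, type_a = type_a, type_b = type_b,
         note = as.character(note)),
    nrow = 1L, class = "correction_factor"
  )
}

#' Percent deviation of a factor from unity
#'
#' `100 * (1 - k)`: the relative dose difference, in percent, that the
#' correction accounts for (e.g. a vertical-position factor of 0.9640
#' means the dose 11 mm below center is 3.6% lower than at center).
#'
#' @param k Factor value or a [correction_factor()] row.
#' @return Signed percent deviation.
#' @export
deviation_from_unity_pct <- function(k) {
  if (inherits(k, "correction_factor") || (is.list(k) && !is.null(k$value))) {
    k <- k$value
  }
  100 * (1 - k)
}

#' Scored core doses from the three calorimeter model configurations
#'
#' Holds the core doses scored by an external transport calculation in the
#' three model geometries used to derive the impurity and gap corrections:
#' the full geometry (thermistors and graphite impurities present), the
#' pure-graphite geometry (impurities replaced by graphite, vacuum gaps
#' kept) and the compensated geometry (gaps removed and back-filled so the
#' medium is homogeneous at unchanged buildup).
#'
#' @param d_full,d_pure,d_compensated Scored core doses, Gy (> 0).
#' @param u_full,u_pure,u_compensated Per-value statistical (Type A)
#'   uncertainties, % at k = 1.
#' @return A `scored_dose_set` list.
#' @export
scored_dose_set <- function(d_full, d_pure, d_compensated,
                            u_full = 0, u_pure = 0, u_compensated = 0) {
  for (v in c(d_full, d_pure, d_compensated)) {
    stop_if_not_scalar_number(v, "scored dose", positive = TRUE)
  }
  structure(
    list(
      d_full = d_full, d_pure = d_pure, d_compensated = d_compensated,
      u_full = u_full, u_pure = u_pure, u_compensated = u_compensated
    ),
    class = "scored_dose_set"
  )
}

#' Impurity and gap correction factors from scored doses
#'
#' `compute_kimp()` is the ratio of the dose scored in the pure-graphite
#' and full geometries (converts dose-to-core-with-impurities to
#' dose-to-pure-graphite); `compute_kgap()` is the ratio of the
#' compensated and pure-graphite geometries (removes the vacuum-gap
#' effect). The per-value statistical uncertainties combine in quadrature
#' into the factor's Type A.
#'
#' @param s A [scored_dose_set()].
#' @param type_b Type B standard uncertainty to attach, % (k = 1);
#'   supplied externally (e.g. from collimator-tilt and ionization
#'   potential sensitivity studies).
#' @return A [correction_factor()].
#' @export
compute_kimp <- function(s, type_b = 0) {
  stopifnot(inherits(s, "scored_dose_set"))
  correction_factor(
    "kimp", s$d_pure / s$d_full,
    type_a = quadrature(c(s$u_pure, s$u_full)),
    type_b = type_b,
    note = "ratio of scored core dose, pure-graphite / full geometry"
  )
}

#' @rdname compute_kimp
#' @export
compute_kgap <- function(s, type_b = 0) {
  stopifnot(inherits(s, "scored_dose_set"))
  correction_factor(
    "kgap", s$d_compensated / s$d_pure,
    type_a = quadrature(c(s$u_compensated, s$u_pure)),
    type_b = type_b,
    note = "ratio of scored core dose, compensated / pure-graphite geometry"
  )
}

#' Vertical-position correction factor from repeated film maps
#'
#' Mean over repeated film dose maps of the ratio between the DAP per unit
#' area of the detector aperture at the mounted position (default
#' (0, -11) mm) and at the field center; the standard deviation of the
#' per-film ratios is the Type A uncertainty. Corrects detector readings
#' at center for comparison with readings at the mounted position in a
#' field that is non-uniform along the beamlets.
#'
#' @param maps List of >= 2 [dose_map()]s (repeated film measurements).
#' @param radius Detector aperture radius, mm (7.8 Roos, 8.0 calorimeter).
#' @param target Mounted detector position (x, y), mm.
#' @param reference Reference position (x, y), mm.
#' @param name Factor name to record.
#' @param type_b Type B uncertainty to attach, % (k = 1), typically from
#'   [positional_type_b_on_factor()].
#' @return A [correction_factor()].
#' @export
compute_kvert <- function(maps, radius, target = c(0, -11),
                          reference = c(0, 0), name = "kvert_roos",
                          type_b = 0) {
  if (!is.list(maps) || length(maps) < 2L) {
    abort("`maps` must be a list of >= 2 repeated film dose maps.")
  }
  ratios <- vapply(maps, function(m) {
    dap_per_area(m, sensitive_region(target[1], target[2], radius)) /
      dap_per_area(m, sensitive_region(reference[1], reference[2], radius))
  }, numeric(1))
  correction_factor(
    name, mean(ratios),
    type_a = 100 * sd(ratios) / mean(ratios),
    type_b = type_b,
    note = sprintf(
      "mean DAP/area ratio (%g, %g)/(%g, %g), r = %g mm, %d films",
      target[1], target[2], reference[1], reference[2], radius, length(maps)
    )
  )
}

#' Profile correction factor between two aperture sizes
#'
#' Mean over repeated film maps of the ratio between the DAP per unit area
#' of the larger and smaller detector footprints at the same center
#' (default 8.0 mm calorimeter core over 7.8 mm plane-parallel chamber at
#' (0, -11) mm); the standard deviation is the Type A uncertainty.
#' Harmonizes detectors of differing sensitive-region size.
#'
#' @param maps List of >= 2 [dose_map()]s.
#' @param center Common aperture center (x, y), mm.
#' @param r_num,r_den Radii of the numerator and denominator apertures, mm.
#' @param type_b Type B uncertainty to attach, % (k = 1).
#' @return A [correction_factor()].
#' @export
compute_kprof <- function(maps, center = c(0, -11), r_num = 8.0, r_den = 7.8,
                          type_b = 0) {
  if (!is.list(maps) || length(maps) < 2L) {
    abort("`maps` must be a list of >= 2 repeated film dose maps.")
  }
  ratios <- vapply(maps, function(m) {
    dap_per_area(m, sensitive_region(center[1], center[2], r_num)) /
      dap_per_area(m, sensitive_region(center[1], center[2], r_den))
  }, numeric(1))
  correction_factor(
    "kprof", mean(ratios),
    type_a = 100 * sd(ratios) / mean(ratios),
    type_b = type_b,
    note = sprintf(
      "mean DAP/area ratio r=%g over r=%g mm at (%g, %g), %d films",
      r_num, r_den, center[1], center[2], length(maps)
    )
  )
}

#' Graphite-to-water dose conversion factor by r80 range scaling
#'
#' Normalizes both depth-dose curves to their own maximum (percentage
#' depth dose), scales the graphite curve's depth axis by the ratio of
#' distal r80 ranges so its range matches that in water, and takes the
#' ratio of the two curves at the reference depth. Curves are interpolated
#' with a shape-preserving monotone cubic.
#'
#' @param pdd_water,pdd_graphite [depth_dose_curve()]s for water and
#'   graphite.
#' @param ref_depth Reference depth in water, mm (20 mm for the
#'   mono-energetic configuration, 100 mm mid-SOBP).
#' @param type_a,type_b Uncertainties to attach, % (k = 1).
#' @return A [correction_factor()] named `dose_conversion`.
#' @export
compute_dose_conversion <- function(pdd_water, pdd_graphite, ref_depth,
                                    type_a = 0, type_b = 0) {
  stop_if_not_scalar_number(ref_depth, "ref_depth", positive = TRUE)
  r80_w <- find_r80(pdd_water)
  r80_g <- find_r80(pdd_graphite)
  scale <- r80_w / r80_g

  zw <- pdd_water$depth_mm
  dw <- pdd_water$dose / max(pdd_water$dose)
  zg <- pdd_graphite$depth_mm * scale
  dg <- pdd_graphite$dose / max(pdd_graphite$dose)

  if (ref_depth > max(zw) || ref_depth > max(zg) ||
      ref_depth < min(zw) || ref_depth < min(zg)) {
    abort("`ref_depth` lies outside one of the curves after range scaling.")
  }
  val <- monotone_interp(zw, dw)(ref_depth) / monotone_interp(zg, dg)(ref_depth)
  correction_factor(
    "dose_conversion", val,
    type_a = type_a, type_b = type_b,
    note = sprintf(
      "PDD ratio water/graphite at %g mm after r80 scaling (x%.5f)",
      ref_depth, scale
    )
  )
}

#' Positioning Type B uncertainty propagated through a film-derived factor
#'
#' The vertical-position and profile corrections are themselves ratios of
#' DAP-per-unit-area values at specific aperture positions, so detector
#' positioning errors perturb them. The two readings entering a factor come
#' from independently positioned set-ups, so per axis an unnormalized DAP
#' offset response is built for each aperture, an independent Gaussian
#' positioning error is sampled for each, the factor is recomputed per
#' sample, and the standard deviation (in %) of the sampled factor values
#' is that axis' Type B contribution; the axes combine in quadrature. With
#' several maps the per-axis standard deviations are averaged over maps
#' before combining.
#'
#' @param maps A [dose_map()] or list of maps.
#' @param factor `"kvert"` or `"kprof"`.
#' @param model A [positioning_model()].
#' @param n_samples Gaussian draws per axis.
#' @param seed Integer seed.
#' @param radius Aperture radius for `kvert`, mm.
#' @param target,reference `kvert` aperture centers (x, y), mm.
#' @param center `kprof` common center (x, y), mm.
#' @param r_num,r_den `kprof` radii, mm.
#' @param scan_halfwidth Half-width of the precomputed offset grid, mm
#'   (samples are clipped to it; default 3 sigma).
#' @return Combined Type B, % (k = 1), with per-axis components as the
#'   `"components"` attribute.
#' @export
positional_type_b_on_factor <- function(maps, factor = c("kvert", "kprof"),
                                        model = positioning_model(),
                                        n_samples = 1e5, seed = 1,
                                        radius = 7.8,
                                        target = c(0, -11),
                                        reference = c(0, 0),
                                        center = c(0, -11),
                                        r_num = 8.0, r_den = 7.8,
                                        scan_halfwidth = 3 * model$sigma) {
  factor <- match.arg(factor)
  if (inherits(maps, "dose_map")) maps <- list(maps)
  grid <- seq(-scan_halfwidth, scan_halfwidth, by = scan_halfwidth / 6)

  # unnormalized DAP response of one aperture to a displacement along `axis`
  dap_response <- function(map, pos, r, axis) {
    vals <- vapply(grid, function(delta) {
      shift <- if (axis == "h") c(delta, 0) else c(0, delta)
      p <- pos + shift
      dap_per_area(map, sensitive_region(p[1], p[2], r))
    }, numeric(1))
    monotone_interp(grid, vals)
  }

  # per-map, per-axis sd of the sampled factor value; the numerator and
  # denominator apertures get independent positioning errors
  axis_sd <- function(map, axis) {
    if (factor == "kvert") {
      f_num <- dap_response(map, target, radius, axis)
      f_den <- dap_response(map, reference, radius, axis)
    } else {
      f_num <- dap_response(map, center, r_num, axis)
      f_den <- dap_response(map, center, r_den, axis)
    }
    clip <- function(d) pmin(pmax(d, min(grid)), max(grid))
    s <- f_num(clip(rnorm(n_samples, 0, model$sigma))) /
      f_den(clip(rnorm(n_samples, 0, model$sigma)))
    100 * sd(s) / mean(s)
  }

  sds <- with_seed(seed, {
    h <- vapply(maps, axis_sd, numeric(1), axis = "h")
    v <- vapply(maps, axis_sd, numeric(1), axis = "v")
    c(h = mean(h), v = mean(v))
  })
  out <- quadrature(sds)
  attr(out, "components") <- sds
  out
}
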
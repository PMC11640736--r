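#' Convert an expanded (k = 2) uncertainty to standard (k = 1)
#'
#' Maximum-deviation sensitivity studies are conventionally reported as
#' expanded uncertainties at k = 2; dividing by 2 expresses them at k = 1
#' so they can enter a quadrature combination with other standard
#' uncertainties.
#'
#' @param max_deviation Expanded uncertainty (k = 2), % (>= 0).
#' @return Standard uncertainty (k = 1), %.
#' @export
#'
#' @examples
#' expanded_to_standard(0.96) # 0.48
expanded_to_standard <- function(max_deviation) {
  if (any(max_deviation < 0)) abort("uncertainties must be >= 0.")
  max_deviation / 2
}

# required factor names per measurement configuration: the mono-energetic
# calorimeter measurement is made at its mounted (0, -11) mm position so no
# vertical correction applies; the SOBP measurement is made at field center
# and needs the calorimeter's own vertical factor.
required_factor_names <- function(config) {
  switch(config,
    mono = c("kimp", "kgap", "dose_conversion"),
    sobp = c("kimp", "kgap", "dose_conversion", "kvert_pspc"),
    abort("`config` must be 'mono' or 'sobp' (or supply `required`).")
  )
}

#' Assemble dose-to-water from the measured core dose
#'
#' Multiplies the measured core dose by the full set of correction
#' factors: the graphite-to-water dose conversion, the impurity and
#' vacuum-gap corrections, and (SOBP configuration) the calorimeter's
#' vertical-position correction. Uncertainties combine in quadrature of
#' all component Type A and Type B terms plus the core-dose measurement
#' uncertainty; for a pure product, relative (fractional) propagation is
#' exact.
#'
#' @param d_core Measured core dose, Gy (> 0).
#' @param factors `correction_factor` rows (a list of them or an already
#'   row-bound tibble), exactly one per required name.
#' @param config `"mono"` or `"sobp"`; sets the required factor names.
#' @param required Optional explicit character vector of required factor
#'   names, overriding `config` (e.g. for a chamber-branch assembly that
#'   carries `kvert_roos`).
#' @param d_core_type_a,d_core_type_b Core-dose measurement uncertainties,
#'   % (k = 1); Type A is typically the empirical sd of repeated trace
#'   analyses.
#' @return A `dose_result` list: `Dw` (Gy), `combined_pct` (k = 1),
#'   `expanded_pct` (k = 2), `components` (tibble of all budget rows).
#' @export
#'
#' @examples
#' fs <- list(
#'   correction_factor("kimp", 1.0013),
#'   correction_factor("kgap", 1.0002),
#'   correction_factor("dose_conversion", 1.1164)
#' )
#' dose_to_water(1.0, fs, config = "mono")
dose_to_water <- function(d_core, factors, config = c("mono", "sobp"),
                          required = NULL,
                          d_core_type_a = 0, d_core_type_b = 0) {
  stop_if_not_scalar_number(as.numeric(d_core), "d_core", positive = TRUE)
  d_core <- as.numeric(d_core)
  if (is.null(required)) required <- required_factor_names(match.arg(config))

  if (inherits(factors, "correction_factor") || is.data.frame(factors)) {
    tbl <- as_tibble(factors)
  } else {
    tbl <- dplyr::bind_rows(lapply(factors, as_tibble))
  }
  dup <- unique(tbl$name[duplicated(tbl$name)])
  if (length(dup) > 0) {
    abort(paste0("duplicate correction factors: ", paste(dup, collapse = ", ")))
  }
  missing <- setdiff(required, tbl$name)
  if (length(missing) > 0) {
    abort(paste0("missing correction factors: ", paste(missing, collapse = ", ")))
  }
  extra <- setdiff(tbl$name, required)
  if (length(extra) > 0) {
    abort(paste0(
      "unexpected correction factors for this configuration: ",
      paste(extra, collapse = ", ")
    ))
  }
  if (any(tbl$value <= 0)) abort("all correction factors must be > 0.")

  components <- dplyr::bind_rows(
    tibble(name = "d_core", value = d_core,
           type_a = d_core_type_a, type_b = d_core_type_b,
           note = "measured core dose"),
    tbl
  )
  dw <- d_core * prod(tbl$value)
  combined <- budget_combined(components)
  structure(
    list(
      Dw = dw,
      combined_pct = combined,
      expanded_pct = 2 * combined,
      components = components
    ),
    class = "dose_result"
  )
}

#' Recompute the combined uncertainty of a budget table
#'
#' Quadrature (k = 1) over every Type A and Type B entry of a component
#' table, so a serialized budget can be re-verified against its stored
#' combined value.
#'
#' @param components Tibble with `type_a` and `type_b` columns, %.
#' @return Combined standard uncertainty, %.
#' @export
budget_combined <- function(components) {
  quadrature(c(components$type_a, components$type_b))
}

#' @export
print.dose_result <- function(x, ...) {
  cat(sprintf("<dose_result> Dw = %.4f Gy, u = %.2f%% (k=1), U = %.2f%% (k=2)\n",
              x$Dw, x$combined_pct, x$expanded_pct))
  print(x$components)
  invisible(x)
}

#' @export
#' @method tidy dose_result
tidy.dose_result <- function(x, ...) {
  x$components
}

#' @export
#' @method glance dose_result
glance.dose_result <- function(x, ...) {
  tibble(
    Dw = x$Dw,
    combined_pct = x$combined_pct,
    expanded_pct = x$expanded_pct,
    n_components = nrow(x$components)
  )
}

#' Serialize and re-read a dose result
#'
#' YAML report of the dose, its uncertainties and the full component
#' table; numbers round-trip bit-exactly via full-precision character
#' encoding.
#'
#' @param result A `dose_result`.
#' @param path YAML path.
#' @return `write_dose_result()` returns `path` invisibly;
#'   `read_dose_result()` returns a `dose_result`.
#' @export
write_dose_result <- function(result, path) {
  num <- function(x) sprintf("%.17g", x)
  yaml::write_yaml(
    list(
      Dw_gy = num(result$Dw),
      combined_pct = num(result$combined_pct),
      expanded_pct = num(result$expanded_pct),
      components = lapply(seq_len(nrow(result$components)), function(i) {
        r <- result$components[i, ]
        list(name = r$name, value = num(r$value),
             type_a = num(r$type_a), type_b = num(r$type_b),
             note = r$note)
      })
    ),
    path
  )
  invisible(path)
}

#' @rdname write_dose_result
#' @export
read_dose_result <- function(path) {
  obj <- yaml::read_yaml(path)
  comp <- dplyr::bind_rows(lapply(obj$components, function(r) {
    tibble(name = r$name, value = as.numeric(r$value),
           type_a = as.numeric(r$type_a), type_b = as.numeric(r$type_b),
           note = r$note %||% "")
  }))
  structure(
    list(
      Dw = as.numeric(obj$Dw_gy),
      combined_pct = as.numeric(obj$combined_pct),
      expanded_pct = as.numeric(obj$expanded_pct),
      components = comp
    ),
    class = "dose_result"
  )
}

#' Calorimeter-to-chamber dose ratio
#'
#' Ratio of the calorimeter dose-to-water to the chamber dose-to-water,
#' with the profile correction applied to harmonize the differing
#' sensitive-region footprints (the chamber reading is multiplied by the
#' profile factor before the ratio). The ratio uncertainty is the
#' quadrature of both results' combined uncertainties and the profile
#' factor's.
#'
#' @param calorimeter,chamber `dose_result`s.
#' @param kprof A [correction_factor()] (profile correction), or `NULL`
#'   for identical footprints.
#' @param label Optional measurement-set label carried into the report row.
#' @return One-row tibble: `label`, `ratio`, `u_pct` (k = 1),
#'   `expanded_pct` (k = 2).
#' @export
ratio_report <- function(calorimeter, chamber, kprof = NULL, label = "") {
  stopifnot(inherits(calorimeter, "dose_result"), inherits(chamber, "dose_result"))
  kp_val <- 1
  kp_u <- 0
  if (!is.null(kprof)) {
    kp_val <- kprof$value
    kp_u <- quadrature(c(kprof$type_a, kprof$type_b))
  }
  ratio <- calorimeter$Dw / (chamber$Dw * kp_val)
  u <- quadrature(c(calorimeter$combined_pct, chamber$combined_pct, kp_u))
  tibble(label = label, ratio = ratio, u_pct = u, expanded_pct = 2 * u)
}

#' Plot grouped calorimeter-to-chamber ratios
#'
#' @param ratios Tibble of [ratio_report()] rows.
#' @param expanded Error bars at k = 2 (default) or k = 1.
#' @return A ggplot object.
#' @export
plot_ratio_report <- function(ratios, expanded = TRUE) {
  u <- if (expanded) ratios$expanded_pct else ratios$u_pct
  df <- dplyr::mutate(ratios,
    lo = .data$ratio * (1 - u / 100),
    hi = .data$ratio * (1 + u / 100)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::labs(x = "measurement set", y = "calorimeter / chamber dose ratio")
}
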
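#' Planar dose map on a regular pixel grid
#'
#' A `dose_map` holds a 2D raster of absorbed dose (Gy) on a regular,
#' cell-centered grid with a physical pixel spacing, in field-centered
#' coordinates: x runs across the beamlets, y along them, y increases
#' upward, so positions below the field center (e.g. a detector mounted
#' 11 mm below isocenter) have negative y.
#'
#' @param values Numeric matrix of dose in Gy; rows are y (row 1 at the top
#'   of the field, i.e. the largest y), columns are x.
#' @param pixel_spacing Pixel pitch in mm. The default corresponds to a
#'   600 dpi film scan (25.4/600 mm).
#' @param origin Length-2 numeric, the (x, y) position in mm of the grid
#'   center relative to the field center. `c(0, 0)` means the grid is
#'   centered on the field.
#'
#' @return An object of class `dose_map`.
#' @export
#'
#' @examples
#' m <- dose_map(matrix(2, 50, 50), pixel_spacing = 0.5)
#' dap_per_area(m, sensitive_region(0, 0, 5))
dose_map <- function(values, pixel_spacing = 25.4 / 600, origin = c(0, 0)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (anyNA(values) || any(values < 0)) {
    abort("dose values must be finite and >= 0 everywhere.")
  }
  stop_if_not_scalar_number(pixel_spacing, "pixel_spacing", positive = TRUE)
  if (!is.numeric(origin) || length(origin) != 2L || anyNA(origin)) {
    abort("`origin` must be a length-2 numeric (x, y) in mm.")
  }
  structure(
    list(
      values = values,
      pixel_spacing = pixel_spacing,
      origin = as.numeric(origin)
    ),
    class = "dose_map"
  )
}

#' @export
print.dose_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<dose_map> %d x %d px, %.5f mm/px (%.1f x %.1f mm), dose %.4g-%.4g Gy\n",
    d[1], d[2], x$pixel_spacing,
    d[2] * x$pixel_spacing, d[1] * x$pixel_spacing,
    min(x$values), max(x$values)
  ))
  invisible(x)
}

# cell-center coordinates (mm, field frame) of columns / rows
map_x_coords <- function(map) {
  n <- ncol(map$values)
  map$origin[1] + (seq_len(n) - (n + 1) / 2) * map$pixel_spacing
}

map_y_coords <- function(map) {
  n <- nrow(map$values)
  map$origin[2] + ((n + 1) / 2 - seq_len(n)) * map$pixel_spacing
}

#' @export
#' @method as_tibble dose_map
as_tibble.dose_map <- function(x, ...) {
  xs <- map_x_coords(x)
  ys <- map_y_coords(x)
  tibble(
    x = rep(xs, each = length(ys)),
    y = rep(ys, times = length(xs)),
    dose = as.vector(x$values)
  )
}

#' Plot a dose map as a raster
#'
#' @param object A [dose_map()].
#' @param downsample Integer stride applied to both axes before plotting
#'   (600 dpi maps are large; the default keeps roughly a 500-px image).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot dose_map
autoplot.dose_map <- function(object, downsample = NULL, ...) {
  d <- dim(object$values)
  downsample <- downsample %||% max(1L, floor(max(d) / 500))
  sub <- object
  sub$values <- object$values[
    seq(1L, d[1], by = downsample),
    seq(1L, d[2], by = downsample),
    drop = FALSE
  ]
  sub$pixel_spacing <- object$pixel_spacing * downsample
  df <- as_tibble.dose_map(sub)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$dose)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "Dose (Gy)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm, across beamlets)", y = "y (mm, along beamlets)")
}

#' @rdname autoplot.dose_map
#' @export
plot_dose_map <- function(object, downsample = NULL, ...) {
  autoplot.dose_map(object, downsample = downsample, ...)
}

# ---------------------------------------------------------------------------
# IO: TIFF + YAML sidecar, and plain CSV grid
# ---------------------------------------------------------------------------

#' Read and write dose maps
#'
#' Dose maps are stored either as a single-channel 32-bit TIFF plus a YAML
#' sidecar (`<path>.yaml`) carrying `pixel_spacing_mm`, `origin_mm` and a
#' `dose_scale_gy` normalization (pixel values are dose/dose_scale so the
#' raster stays in \[0, 1\]), or as a plain CSV grid of dose values with the
#' same sidecar. CSV is lossless text; TIFF round-trips within float32
#' precision.
#'
#' @param map A [dose_map()].
#' @param path Output file path (`.tiff` or `.csv`).
#' @return `write_dose_map()` returns `path` invisibly; `read_dose_map()`
#'   returns a [dose_map()].
#' @export
write_dose_map <- function(map, path) {
  stopifnot(inherits(map, "dose_map"))
  scale <- max(map$values, 1e-300)
  sidecar <- list(
    pixel_spacing_mm = map$pixel_spacing,
    origin_mm = as.numeric(map$origin),
    dose_scale_gy = scale
  )
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.table(map$values, path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    sidecar$dose_scale_gy <- 1
  } else {
    tiff::writeTIFF(map$values / scale, path, bits.per.sample = 32L)
  }
  yaml::write_yaml(sidecar, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_dose_map
#' @param path File previously written by `write_dose_map()`.
#' @export
read_dose_map <- function(path) {
  sidecar <- yaml::read_yaml(paste0(path, ".yaml"))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    values <- as.matrix(utils::read.table(path, sep = ","))
    dimnames(values) <- NULL
  } else {
    values <- tiff::readTIFF(path) * sidecar$dose_scale_gy
  }
  dose_map(values,
    pixel_spacing = sidecar$pixel_spacing_mm,
    origin = as.numeric(sidecar$origin_mm)
  )
}
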
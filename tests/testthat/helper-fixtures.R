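# Shared fixtures and independent oracles. Fixture maps are noiseless and
# rasterized at 0.1 mm (coarser than a 600 dpi scan, fine relative to every
# structure in the field); they are built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

mono_spec <- function(noise_sd = 0, ...) {
  minibeam_field_spec(blur_sigma = 0.9, valley_fraction = 0.05,
                      noise_sd = noise_sd, ...)
}

sobp_spec <- function(noise_sd = 0, ...) {
  minibeam_field_spec(blur_sigma = 1.3, valley_fraction = 0.10,
                      noise_sd = noise_sd, ...)
}

cache <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

mono_map <- function() {
  cache("mono", generate_minibeam_map(mono_spec(), pixel_spacing = 0.1))
}

sobp_map <- function() {
  cache("sobp", generate_minibeam_map(sobp_spec(), pixel_spacing = 0.1))
}

# padded raster so the 40.8 mm aperture at (0, -11) stays in bounds
mono_map_wide <- function() {
  cache("mono_wide",
        generate_minibeam_map(mono_spec(), pixel_spacing = 0.1,
                              grid_extent = c(112, 112)))
}

# Brute-force supersampled disc integrator: every pixel value is treated as
# constant over its cell and probed at k x k subpixel centers; the mean over
# all probe points inside the circle is the oracle value. Independent of the
# boundary-classification logic in dap_per_area.
dap_oracle <- function(map, cx, cy, r, k = 16) {
  ps <- map$pixel_spacing
  xs <- minibeamdose:::map_x_coords(map)
  ys <- minibeamdose:::map_y_coords(map)
  jj <- which(abs(xs - cx) <= r + ps)
  ii <- which(abs(ys - cy) <= r + ps)
  sub <- map$values[ii, jj, drop = FALSE]
  dx <- xs[jj] - cx
  dy <- ys[ii] - cy
  off <- (seq_len(k) - (k + 1) / 2) / k * ps
  total <- 0
  count <- 0
  for (ox in off) {
    x2 <- (dx + ox)^2
    for (oy in off) {
      inside <- outer((dy + oy)^2, x2, `+`) <= r^2
      total <- total + sum(sub[inside])
      count <- count + sum(inside)
    }
  }
  total / count
}

# assemble a synthetic offset scan (bypasses DAP computation) so Type B
# sampling can be tested against closed forms
make_scan <- function(offsets, values, axis = "horizontal", reference = offsets[1]) {
  out <- tibble::new_tibble(
    list(offset = as.numeric(offsets), dap = as.numeric(values),
         value = as.numeric(values)),
    nrow = length(offsets), class = "offset_scan"
  )
  attr(out, "axis") <- axis
  attr(out, "reference") <- reference
  attr(out, "radius") <- NA_real_
  out
}

# uniform dose map helper
uniform_map <- function(value = 2, n = 240, ps = 0.25) {
  dose_map(matrix(value, n, n), pixel_spacing = ps)
}
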
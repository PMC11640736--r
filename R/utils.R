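#' @importFrom rlang abort warn .data %||%
#' @importFrom stats pnorm dnorm qnorm sd lm coef predict approx splinefun rnorm
#' @importFrom tibble tibble as_tibble is_tibble new_tibble
#' @importFrom ggplot2 autoplot
#' @importFrom generics tidy glance
#' @importFrom utils head tail
NULL

#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance

# shared argument checks -------------------------------------------------

stop_if_not_scalar_number <- function(x, name, positive = FALSE,
                                      nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0 (got %g).", name, x))
  }
  if (nonnegative && x < 0) {
    abort(sprintf("`%s` must be >= 0 (got %g).", name, x))
  }
  invisible(x)
}

# Monotone (Fritsch-Carlson) cubic interpolator; shape-preserving, used for
# offset scans and depth-dose curves.
monotone_interp <- function(x, y) {
  splinefun(x, y, method = "monoH.FC")
}

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG so generators never perturb user-level reproducibility.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}
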
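# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed without touching global state
#'
#' All stochastic operations in the package take explicit `seed` arguments and
#' route through this helper, so a user's `.Random.seed` is left untouched and
#' identical seeds give byte-identical outputs.
#'
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stage seed from a master seed; kept below 2^31 - 1.
derive_seed <- function(seed, k) {
  (as.double(seed) * 48271 + 101 * k) %% 2147483647
}

stop_validation <- function(...) {
  stop(structure(
    class = c("retnathist_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_validation(...)
  invisible(TRUE)
}

#' Smooth zero-mean random field on a 1-D grid
#'
#' White noise on a coarse grid (one knot per `knot_spacing`) linearly
#' interpolated to `x`, then recentred to sample mean 0 and rescaled to sample
#' SD `sd`.  Used for within-eye thickness variation along a meridian so that a
#' phantom eye's realised profile mean/SD equal the configured values exactly.
#' @keywords internal
smooth_field_1d <- function(x, sd, knot_spacing) {
  if (sd <= 0 || length(x) < 3L) return(numeric(length(x)))
  rng <- range(x)
  knots <- seq(rng[1] - knot_spacing, rng[2] + knot_spacing,
               by = knot_spacing)
  if (length(knots) < 4L) knots <- seq(rng[1] - knot_spacing, rng[2] + knot_spacing, length.out = 4L)
  vals <- stats::rnorm(length(knots))
  f <- stats::approx(knots, vals, xout = x, rule = 2)$y
  f <- f - mean(f)
  s <- stats::sd(f)
  if (s < .Machine$double.eps) return(numeric(length(x)))
  f * (sd / s)
}

# Smooth zero-mean random field on a 2-D grid (bilinear from coarse knots),
# recentred/rescaled like smooth_field_1d.  x, y are the grid axes (mm).
smooth_field_2d <- function(y, x, sd, knot_spacing) {
  ny <- length(y); nx <- length(x)
  if (sd <= 0) return(matrix(0, ny, nx))
  ky <- seq(min(y) - knot_spacing, max(y) + knot_spacing, by = knot_spacing)
  kx <- seq(min(x) - knot_spacing, max(x) + knot_spacing, by = knot_spacing)
  if (length(ky) < 2L) ky <- c(min(y) - knot_spacing, max(y) + knot_spacing)
  if (length(kx) < 2L) kx <- c(min(x) - knot_spacing, max(x) + knot_spacing)
  vals <- matrix(stats::rnorm(length(ky) * length(kx)), length(ky), length(kx))
  # bilinear interpolation, vectorised per axis
  iy <- findInterval(y, ky, all.inside = TRUE)
  ix <- findInterval(x, kx, all.inside = TRUE)
  wy <- (y - ky[iy]) / (ky[iy + 1L] - ky[iy])
  wx <- (x - kx[ix]) / (kx[ix + 1L] - kx[ix])
  a <- vals[iy, ix, drop = FALSE]
  b <- vals[iy + 1L, ix, drop = FALSE]
  cc <- vals[iy, ix + 1L, drop = FALSE]
  d <- vals[iy + 1L, ix + 1L, drop = FALSE]
  W_y <- matrix(wy, ny, nx)
  W_x <- matrix(wx, ny, nx, byrow = TRUE)
  f <- a * (1 - W_y) * (1 - W_x) + b * W_y * (1 - W_x) +
    cc * (1 - W_y) * W_x + d * W_y * W_x
  f <- f - mean(f)
  s <- stats::sd(as.vector(f))
  if (s < .Machine$double.eps) return(matrix(0, ny, nx))
  f * (sd / s)
}

# Gaussian smoothing of a vector (reflective boundary), sigma in samples.
gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rev(x[seq_len(half)]), x, rev(x[seq(n - half + 1L, n)]))
  stats::filter(xp, k, sides = 2)[(half + 1L):(half + n)]
}
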
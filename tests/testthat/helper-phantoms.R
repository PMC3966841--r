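# Shared fixture factories.  All phantoms are generated at desk scale
# (small rasters / short line scans) so the suite stays fast; geometry and
# noise parameters are the package defaults unless a test states otherwise.

small_linescan <- function(seed = 1L, noise_sd = 0.02, n_lrps = 120L,
                           onl_mean = 66.4, onl_sd = 5.4,
                           total_mean = 197.4, total_sd = 9.2,
                           rosettes = c(all = 0), n_repeats = 1L, ...) {
  # rosettes = NULL selects the phantom's default (printed) densities
  oct_phantom_params(
    scan_mode = "linescan", n_bscans = n_repeats, n_repeats = n_repeats,
    n_lrps_per_bscan = n_lrps, axial_px = 256L, field_diameter = 2.4,
    onl_thickness_mean = onl_mean, onl_thickness_sd = onl_sd,
    total_thickness_mean = total_mean, total_thickness_sd = total_sd,
    noise_sd = noise_sd,
    rosette_density_by_sector = rosettes,
    seed = seed, ...)
}

small_raster <- function(seed = 1L, px = 100L, noise_sd = 0.02,
                         counts = NULL, densities = NULL, ...) {
  oct_phantom_params(
    scan_mode = "raster", n_bscans = px, n_lrps_per_bscan = px,
    axial_px = 224L, axial_scale = 1.8, field_diameter = 1.5,
    rosette_count_by_sector = counts,
    rosette_density_by_sector = densities %||%
      if (is.null(counts)) c(all = 0) else NULL,
    noise_sd = noise_sd, seed = seed, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian smoother for building band-limited random test signals.
gauss_smooth_r <- function(x, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rev(x[seq_len(half)]), x, rev(x[seq(n - half + 1L, n)]))
  as.numeric(stats::filter(xp, k, sides = 2)[(half + 1L):(half + n)])
}

with_seed_r <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Independent brute-force prominence oracle: for every strict local maximum,
# walk out to the nearest higher samples on each side and take the drop to
# the higher of the two intervening minima (edge rule: min to the edge).
oracle_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  out <- data.frame(index = integer(0), height = numeric(0),
                    prominence = numeric(0))
  for (i in 2:(n - 1)) {
    if (!(x[i] > x[i - 1] && x[i] >= x[i + 1])) next
    left <- x[seq_len(i - 1)]
    higher_l <- which(left > x[i])
    lmin <- if (length(higher_l)) min(x[(max(higher_l)):(i)]) else min(x[1:i])
    right <- x[(i + 1):n]
    higher_r <- which(right > x[i])
    rmin <- if (length(higher_r)) min(x[i:(i + min(higher_r))]) else min(x[i:n])
    prom <- x[i] - max(lmin, rmin)
    if (prom >= min_prominence)
      out <- rbind(out, data.frame(index = i, height = x[i],
                                   prominence = prom))
  }
  out
}
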
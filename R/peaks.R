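#' Local extrema with topographic prominence
#'
#' Finds local maxima of a 1-D signal and computes each peak's prominence:
#' the drop from the peak height to the highest of the two key saddles, where
#' each saddle is the minimum of the signal between the peak and the nearest
#' higher point on that side (or the signal edge if no higher point exists).
#' This is the standard definition used by peak pickers in signal-processing
#' toolkits; it is re-implemented here because retinal band identification is
#' the core of the layer-segmentation contract and is cross-checked in the
#' tests against a brute-force enumeration oracle.
#'
#' @param x numeric vector (length >= 3).
#' @param min_prominence keep only peaks with prominence >= this value.
#' @return data.frame with columns `index`, `height`, `prominence`, ordered by
#'   `index` (vitreal to sclerad when `x` is an LRP).
#' @export
#' @examples
#' p <- find_peaks(c(0, 1, 0, 3, 0, 2, 0), min_prominence = 0.5)
#' p$index
find_peaks <- function(x, min_prominence = 0) {
  x <- as.numeric(x)
  n <- length(x)
  check_that(n >= 3L, "find_peaks: signal must have length >= 3")
  check_that(all(is.finite(x)), "find_peaks: signal must be finite")
  # local maxima: strictly above previous sample, >= next (left edge of plateaus)
  up <- c(FALSE, diff(x) > 0)
  down <- c(x[-n] >= x[-1], FALSE)
  idx <- which(up & down)
  if (length(idx) == 0L) {
    return(data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0)))
  }
  prom <- vapply(idx, function(i) {
    h <- x[i]
    # left saddle
    j <- i - 1L
    left_min <- h
    while (j >= 1L && x[j] <= h) {
      if (x[j] < left_min) left_min <- x[j]
      j <- j - 1L
    }
    if (j < 1L) left_min <- min(x[seq_len(i)])
    # right saddle
    j <- i + 1L
    right_min <- h
    while (j <= n && x[j] <= h) {
      if (x[j] < right_min) right_min <- x[j]
      j <- j + 1L
    }
    if (j > n) right_min <- min(x[i:n])
    h - max(left_min, right_min)
  }, numeric(1))
  keep <- prom >= min_prominence
  data.frame(index = idx[keep], height = x[idx[keep]], prominence = prom[keep])
}

#' Local minima (troughs) with prominence, via the inverted signal
#'
#' @inheritParams find_peaks
#' @return data.frame with columns `index`, `depth` (signal value at the
#'   trough) and `prominence` (of the inverted peak).
#' @export
find_troughs <- function(x, min_prominence = 0) {
  p <- find_peaks(-as.numeric(x), min_prominence = min_prominence)
  data.frame(index = p$index, depth = -p$height, prominence = p$prominence)
}
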
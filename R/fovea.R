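# Human foveal-island structural metrics and structure-function regressions.

#' Construct a foveal ONL profile
#'
#' @param eccentricity_mm signed eccentricities (mm), strictly increasing.
#' @param onl_um ONL thickness (um), all >= 0.
#' @param meridian `"horizontal"` or `"vertical"`; recorded so downstream
#'   tables know which meridian the metrics were computed along.
#' @return `foveal_profile` data.frame.
#' @export
foveal_profile <- function(eccentricity_mm, onl_um,
                           meridian = c("horizontal", "vertical")) {
  meridian <- match.arg(meridian)
  check_that(all(diff(eccentricity_mm) > 0),
             "eccentricities must be strictly increasing")
  check_that(all(onl_um >= 0), "ONL thickness must be >= 0")
  prof <- data.frame(eccentricity_mm = eccentricity_mm, onl_um = onl_um)
  attr(prof, "meridian") <- meridian
  class(prof) <- c("foveal_profile", "data.frame")
  prof
}

#' Five-sample foveal ONL average
#'
#' Mean of the ONL thickness at the foveal pit and at 0.15 and 0.3 mm
#' eccentricity on each side (five samples), linearly interpolated when the
#' profile grid does not land exactly on those eccentricities.
#'
#' @param profile a `foveal_profile` covering at least +-0.3 mm.
#' @return foveal ONL average (um).
#' @export
foveal_onl_average <- function(profile) {
  x <- profile$eccentricity_mm
  check_that(min(x) <= -0.3 - 1e-9 || abs(min(x) + 0.3) < 1e-6,
             "profile must cover -0.3 mm")
  check_that(max(x) >= 0.3 - 1e-6, "profile must cover +0.3 mm")
  at <- c(-0.3, -0.15, 0, 0.15, 0.3)
  v <- stats::approx(x, profile$onl_um, xout = at)$y
  check_that(!anyNA(v), "profile must cover +-0.3 mm")
  mean(v)
}

#' Foveal island width at half-maximum ONL
#'
#' The retinal distance between the two outermost points at half the maximum
#' ONL thickness, one on each side of the peak, with linear interpolation
#' between grid samples.  Outermost crossings are used so satellite bumps do
#' not shrink the island.  When either side never crosses half-maximum
#' (e.g. a flat or high-baseline profile), the width is undefined:
#' `NA` with attribute `defined = FALSE` (mirroring patients in whom the
#' metric cannot be measured).
#'
#' @param profile a `foveal_profile` with a positive maximum.
#' @return width (mm), or `NA_real_` with attribute `defined = FALSE`.
#' @export
island_width_half_max <- function(profile) {
  x <- profile$eccentricity_mm
  v <- profile$onl_um
  check_that(max(v) > 0, "profile maximum must be > 0")
  ipk <- which.max(v)
  half <- v[ipk] / 2
  undefined <- structure(NA_real_, defined = FALSE)
  cross_out <- function(idx_range, from_outside) {
    # signed crossings of `half` along idx_range; returns interpolated x of
    # the outermost crossing, or NA
    s <- v[idx_range] - half
    cr <- which(s[-length(s)] * s[-1] < 0 |
                  (s[-length(s)] == 0 & s[-1] != 0))
    if (!length(cr)) return(NA_real_)
    k <- if (from_outside) cr[1L] else cr[length(cr)]
    i1 <- idx_range[k]; i2 <- idx_range[k + 1L]
    x[i1] + (x[i2] - x[i1]) * (half - v[i1]) / (v[i2] - v[i1])
  }
  left <- if (ipk > 1L) cross_out(seq_len(ipk), from_outside = TRUE)
          else NA_real_
  right <- if (ipk < length(v)) cross_out(ipk:length(v), from_outside = FALSE)
           else NA_real_
  if (is.na(left) || is.na(right)) return(undefined)
  structure(right - left, defined = TRUE)
}

#' Lower limit of normal from a normative cohort
#'
#' `mean - 2 * sd`: the conventional lower bound of the normal range.
#'
#' @param mean,sd normative cohort mean and SD (um), `sd >= 0`.
#' @return lower limit (um).
#' @export
normal_limits <- function(mean, sd) {
  check_that(sd >= 0, "sd must be >= 0")
  mean - 2 * sd
}

#' Ordinary least squares with a two-sided test on the slope
#'
#' @param x,y numeric vectors, `n >= 3`, `x` not constant.
#' @return list with `slope`, `intercept`, `r_squared`, `p_slope`, `n`.
#' @export
regression_with_slope_test <- function(x, y) {
  check_that(length(x) == length(y) && length(x) >= 3L, "need n >= 3")
  check_that(stats::sd(x) > 0, "x must not be constant")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       p_slope = sm$coefficients[2L, 4L],
       n = length(x))
}

#' Encode off-scale visual acuity categories
#'
#' Hand motions (HM), light perception (LP) and no light perception (NLP)
#' lie beyond the logMAR scale.  They are mapped to ordinal codes (HM = 2.3,
#' LP = 2.6, NLP = 2.9) for plotting and binning only; regression on acuity
#' should use measurable logMAR values unless `allow_offscale = TRUE`.
#'
#' @param acuity character or numeric vector; numeric entries are logMAR.
#' @return numeric vector of logMAR values / ordinal codes.
#' @export
encode_acuity <- function(acuity) {
  codes <- c(HM = 2.3, LP = 2.6, NLP = 2.9)
  out <- suppressWarnings(as.numeric(acuity))
  isch <- is.na(out) & !is.na(acuity)
  out[isch] <- codes[toupper(trimws(as.character(acuity[isch])))]
  check_that(!anyNA(out[!is.na(acuity)]),
             "unrecognised acuity category (expected logMAR, HM, LP or NLP)")
  out
}
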
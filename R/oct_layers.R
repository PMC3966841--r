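# Outer-retinal layer segmentation from longitudinal reflectivity profiles
# (LRPs), RPE flattening, thickness profiles and cohort statistics.
#
# Boundary definitions: total retinal thickness runs from the vitreoretinal
# interface to the RPE peak; ONL+ (photoreceptor layer) runs from the signal
# trough delimited by the peak on the sclerad side of the outer plexiform
# layer to the signal trough vitreal to the hyperreflective RPE band.  The
# RPE is identified as the second hyperreflective band from the scleral side.

#' Extract averaged LRPs from an OCT volume
#'
#' Repeat frames acquired at the same location are averaged pointwise
#' (high-resolution scans are conventionally acquired four times and
#' averaged).
#'
#' @param volume an `oct_volume`.
#' @param repeats number of stored repeat frames per location; must divide
#'   the number of stored B-scans.
#' @return list of LRP objects (class `lrp`): `reflectivity`, `axial_scale`
#'   (um/px), `lateral_position` (mm, signed relative to the ONH; positive =
#'   superior for vertical scans) and `location` (B-scan location index).
#' @export
extract_lrps <- function(volume, repeats = volume$n_repeats) {
  check_that(inherits(volume, "oct_volume"), "volume must be an oct_volume")
  d <- dim(volume$data)
  check_that(d[1] %% repeats == 0L,
             "repeats (", repeats, ") must divide the stored B-scan count (",
             d[1], ")")
  n_loc <- d[1] %/% repeats
  n <- d[2]
  pos <- (seq_len(n) - (n + 1) / 2) * volume$lateral_scale
  out <- vector("list", n_loc * n)
  k <- 0L
  for (loc in seq_len(n_loc)) {
    rows <- (loc - 1L) * repeats + seq_len(repeats)
    block <- volume$data[rows, , , drop = FALSE]
    avg <- if (repeats > 1L) apply(block, c(2, 3), mean) else
      array(block, dim = d[2:3])
    for (i in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- structure(list(reflectivity = avg[i, ],
                                 axial_scale = volume$axial_scale,
                                 lateral_position = pos[i],
                                 location = loc), class = "lrp")
    }
  }
  out
}

#' Locate the RPE band in a single LRP
#'
#' The RPE is the second hyperreflective band encountered scanning from the
#' scleral (deep) end of the profile toward the vitreous, among peaks whose
#' prominence reaches `min_prominence`.
#'
#' @param lrp an `lrp` object (or numeric reflectivity vector, with
#'   `axial_scale` supplied).
#' @param min_prominence prominence threshold; default 10% of the profile's
#'   dynamic range.
#' @param smooth_sigma Gaussian pre-smoothing sigma in pixels.
#' @param axial_scale um/pixel, for numeric-vector input.
#' @return RPE depth in um, or `NA_real_` when fewer than two qualifying
#'   peaks exist (failed segmentation, not an error).
#' @export
find_rpe <- function(lrp, min_prominence = NULL, smooth_sigma = 1.5,
                     axial_scale = NULL) {
  if (inherits(lrp, "lrp")) {
    x <- lrp$reflectivity
    axial_scale <- lrp$axial_scale
  } else {
    x <- as.numeric(lrp)
    check_that(!is.null(axial_scale), "axial_scale required for vector input")
  }
  check_that(length(x) >= 3L && axial_scale > 0, "invalid LRP")
  xs <- gauss_smooth(x, smooth_sigma)
  if (is.null(min_prominence)) min_prominence <- 0.1 * diff(range(xs))
  pk <- find_peaks(xs, min_prominence = min_prominence)
  if (nrow(pk) < 2L) return(NA_real_)
  idx <- sort(pk$index, decreasing = TRUE)[2L]
  idx <- refine_extremum(x, idx, minimum = FALSE)
  (idx - 1L) * axial_scale
}

# Coarse-to-fine: smoothing locates the extremum robustly but can shift it by
# a pixel; re-centre on the unsmoothed signal within +-2 px.
refine_extremum <- function(x, idx, minimum, halfwin = 2L) {
  lo <- max(1L, idx - halfwin)
  hi <- min(length(x), idx + halfwin)
  seg <- x[lo:hi]
  lo - 1L + if (minimum) which.min(seg) else which.max(seg)
}

#' Segment outer-retinal boundaries of a single LRP
#'
#' Identifies, in order from the vitreous: the vitreoretinal interface (first
#' prominent peak), the trough sclerad of the OPL peak, the S+ scattering
#' band, the trough vitreal to the RPE, and the RPE peak.  ONL+ thickness is
#' the distance between the two troughs; total thickness the distance from
#' the interface to the RPE peak.
#'
#' Pseudorosette screening (`rosette_check = TRUE`) flags an A-scan as
#' `excluded_rosette` when (a) two or more prominent peaks fall strictly
#' between the two ONL+ troughs (one, the S+ band, is normal anatomy), or
#' (b) a hyperreflective peak at `>= rosette_height_frac` of the RPE peak
#' height occurs between the interface and the pre-RPE trough — a bright
#' rosette disrupts band identification itself, so the interval rule alone
#' cannot catch it.
#'
#' @inheritParams find_rpe
#' @param rpe RPE depth in um (from [find_rpe()]); computed if `NULL`.
#' @param trough_prominence prominence threshold for troughs; default 2% of
#'   the dynamic range (the boundary troughs are shallow relative to bands).
#' @param rosette_check logical; screen for hyperreflective rosette loci.
#' @param rosette_height_frac height fraction of the RPE peak above which an
#'   interior peak is called a rosette.
#' @return object of class `layer_segmentation`: depths in um
#'   (`vitreoretinal_interface`, `opl_sclerad_trough`, `pre_rpe_trough`,
#'   `rpe_peak`), `onl_plus_um`, `total_um`, and `quality_flag` in
#'   `ok`, `excluded_rosette`, `failed`.
#' @export
segment_onl_plus <- function(lrp, rpe = NULL, min_prominence = NULL,
                             smooth_sigma = 1.5, trough_prominence = NULL,
                             rosette_check = TRUE,
                             rosette_height_frac = 0.75,
                             axial_scale = NULL) {
  if (inherits(lrp, "lrp")) {
    x <- lrp$reflectivity
    axial_scale <- lrp$axial_scale
  } else {
    x <- as.numeric(lrp)
    check_that(!is.null(axial_scale), "axial_scale required for vector input")
  }
  fail <- function(flag) structure(
    list(vitreoretinal_interface = NA_real_, opl_sclerad_trough = NA_real_,
         pre_rpe_trough = NA_real_, rpe_peak = rpe, onl_plus_um = NA_real_,
         total_um = NA_real_, quality_flag = flag),
    class = "layer_segmentation")
  xs <- gauss_smooth(x, smooth_sigma)
  rng <- diff(range(xs))
  if (is.null(min_prominence)) min_prominence <- 0.1 * rng
  if (is.null(trough_prominence)) trough_prominence <- 0.02 * rng
  if (is.null(rpe)) rpe <- find_rpe(xs, min_prominence = min_prominence,
                                    smooth_sigma = 0, axial_scale = axial_scale)
  if (is.na(rpe)) return(fail("failed"))
  rpe_idx <- round(rpe / axial_scale) + 1L
  pk <- find_peaks(xs, min_prominence = min_prominence)
  inner_pk <- pk[pk$index < rpe_idx, , drop = FALSE]
  if (nrow(inner_pk) < 3L) return(fail("failed"))
  vri_idx <- inner_pk$index[1L]
  splus_idx <- inner_pk$index[nrow(inner_pk)]
  opl_idx <- inner_pk$index[nrow(inner_pk) - 1L]
  # trough vitreal to the RPE band (between S+ and RPE)
  t2_idx <- pick_trough(xs, splus_idx, rpe_idx, trough_prominence,
                        first = FALSE)
  # first trough sclerad of the OPL peak (between OPL and S+)
  t1_idx <- pick_trough(xs, opl_idx, splus_idx, trough_prominence,
                        first = TRUE)
  if (is.na(t1_idx) || is.na(t2_idx)) return(fail("failed"))
  flag <- "ok"
  if (rosette_check) {
    rpe_h <- xs[rpe_idx]
    mid <- inner_pk[inner_pk$index > vri_idx & inner_pk$index < t2_idx, ,
                    drop = FALSE]
    n_between <- sum(inner_pk$index > t1_idx & inner_pk$index < t2_idx)
    if (n_between >= 2L || any(mid$height >= rosette_height_frac * rpe_h))
      flag <- "excluded_rosette"
  }
  vri_idx <- refine_extremum(x, vri_idx, minimum = FALSE)
  rpe_idx <- refine_extremum(x, rpe_idx, minimum = FALSE)
  t1_idx <- refine_extremum(x, t1_idx, minimum = TRUE)
  t2_idx <- refine_extremum(x, t2_idx, minimum = TRUE)
  if (!(vri_idx < t1_idx && t1_idx < t2_idx && t2_idx < rpe_idx))
    return(fail("failed"))
  structure(list(
    vitreoretinal_interface = (vri_idx - 1L) * axial_scale,
    opl_sclerad_trough = (t1_idx - 1L) * axial_scale,
    pre_rpe_trough = (t2_idx - 1L) * axial_scale,
    rpe_peak = rpe,
    onl_plus_um = (t2_idx - t1_idx) * axial_scale,
    total_um = (rpe_idx - vri_idx) * axial_scale,
    quality_flag = flag
  ), class = "layer_segmentation")
}

# Trough between two peak indices: the first (most vitreal, `first = TRUE`)
# or last prominent trough in the open interval; falls back to the interval
# argmin when no trough clears the prominence threshold.
pick_trough <- function(xs, from_idx, to_idx, trough_prominence, first) {
  if (to_idx - from_idx < 3L) return(NA_integer_)
  tr <- find_troughs(xs, min_prominence = trough_prominence)
  tr <- tr$index[tr$index > from_idx & tr$index < to_idx]
  if (length(tr)) {
    if (first) tr[1L] else tr[length(tr)]
  } else {
    seg <- xs[(from_idx + 1L):(to_idx - 1L)]
    from_idx + which.min(seg)
  }
}

#' Segment every A-scan of a volume
#'
#' Averages repeat frames, runs [find_rpe()] and [segment_onl_plus()] on each
#' LRP, and returns a per-A-scan table.
#'
#' @param volume an `oct_volume` (linescan mode).
#' @param ... passed to [segment_onl_plus()].
#' @return data.frame with `lateral_position` (mm), boundary depths (um),
#'   `onl_plus_um`, `total_um`, `quality_flag`.
#' @export
segment_volume <- function(volume, ...) {
  lrps <- extract_lrps(volume)
  rows <- lapply(lrps, function(l) {
    s <- segment_onl_plus(l, ...)
    data.frame(lateral_position = l$lateral_position,
               vitreoretinal_interface = s$vitreoretinal_interface,
               opl_sclerad_trough = s$opl_sclerad_trough,
               pre_rpe_trough = s$pre_rpe_trough,
               rpe_peak = if (is.null(s$rpe_peak)) NA_real_ else s$rpe_peak,
               onl_plus_um = s$onl_plus_um, total_um = s$total_um,
               quality_flag = s$quality_flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Thickness profile container
#'
#' @param positions signed positions (mm) relative to the ONH centre,
#'   strictly increasing; positive = superior for vertical meridians.
#' @param values thickness (um).
#' @param mask logical validity per position.
#' @return object of class `thickness_profile` (a data.frame with columns
#'   `position_mm`, `value_um`, `mask`).
#' @export
thickness_profile <- function(positions, values, mask = NULL) {
  check_that(length(positions) == length(values), "length mismatch")
  check_that(all(diff(positions) > 0), "positions must be strictly increasing")
  if (is.null(mask)) mask <- is.finite(values)
  check_that(all(is.finite(values[mask])), "masked-in values must be finite")
  structure(data.frame(position_mm = positions, value_um = values,
                       mask = mask),
            class = c("thickness_profile", "data.frame"))
}

#' Build a thickness profile from a per-A-scan segmentation table
#'
#' A-scans not flagged `ok` are masked out; the optic nerve head exclusion is
#' applied by [exclude_regions()], not here.
#'
#' @param seg output of [segment_volume()].
#' @param what `"onl_plus"` or `"total"`.
#' @export
profile_from_segmentation <- function(seg, what = c("onl_plus", "total")) {
  what <- match.arg(what)
  v <- if (what == "onl_plus") seg$onl_plus_um else seg$total_um
  ok <- seg$quality_flag == "ok" & is.finite(v)
  thickness_profile(seg$lateral_position, v, ok)
}

#' Flatten a volume by straightening the RPE reflection
#'
#' Each A-scan is shifted by an integer number of axial pixels so the RPE
#' band sits at a common depth (the median RPE depth).  Failed A-scans (no
#' RPE found) are interpolated from their neighbours; more than 10% failures
#' is an error.
#'
#' @param volume an `oct_volume`.
#' @param rpe_depths optional per-A-scan RPE depths in um, shaped
#'   `(n_locations x n_lrps)` for linescans or `(n_bscans x n_lrps)` for
#'   rasters; computed with [find_rpe()] on averaged LRPs when `NULL`.
#' @param subsample run [find_rpe()] on every `subsample`-th A-scan in each
#'   direction and interpolate the (smooth) RPE depth field in between; 1 =
#'   every A-scan.
#' @param ... passed to [find_rpe()].
#' @return the flattened `oct_volume`, with attribute `shift_px` (the
#'   per-A-scan integer shift map) and `rpe_target_um` (common RPE depth).
#' @export
flatten <- function(volume, rpe_depths = NULL, subsample = 1L, ...) {
  check_that(inherits(volume, "oct_volume"), "volume must be an oct_volume")
  d <- dim(volume$data)
  repeats <- if (volume$scan_mode == "linescan") volume$n_repeats else 1L
  n_loc <- d[1] %/% repeats
  if (is.null(rpe_depths)) {
    cols <- unique(c(seq(1L, d[2], by = subsample), d[2]))
    locs <- unique(c(seq(1L, n_loc, by = subsample), n_loc))
    coarse <- matrix(NA_real_, length(locs), length(cols))
    for (li in seq_along(locs)) {
      rows <- (locs[li] - 1L) * repeats + seq_len(repeats)
      avg <- if (repeats > 1L)
        apply(volume$data[rows, , , drop = FALSE], c(2, 3), mean)
      else array(volume$data[rows, , , drop = FALSE], dim = d[2:3])
      for (ci in seq_along(cols))
        coarse[li, ci] <- find_rpe(avg[cols[ci], ],
                                   axial_scale = volume$axial_scale, ...)
    }
    if (subsample > 1L) {
      # expand the smooth RPE field: along columns, then along locations
      wide <- matrix(NA_real_, length(locs), d[2])
      for (li in seq_along(locs)) {
        ok <- is.finite(coarse[li, ])
        wide[li, ] <- if (sum(ok) >= 2L)
          stats::approx(cols[ok], coarse[li, ok], xout = seq_len(d[2]),
                        rule = 2)$y
        else NA_real_
      }
      rpe_depths <- matrix(NA_real_, n_loc, d[2])
      for (i in seq_len(d[2])) {
        ok <- is.finite(wide[, i])
        rpe_depths[, i] <- if (sum(ok) >= 2L)
          stats::approx(locs[ok], wide[ok, i], xout = seq_len(n_loc),
                        rule = 2)$y
        else if (sum(ok) == 1L) wide[ok, i]
        else NA_real_
      }
    } else {
      rpe_depths <- coarse
    }
  }
  rpe_depths <- matrix(rpe_depths, nrow = n_loc)
  n_bad <- sum(!is.finite(rpe_depths))
  check_that(n_bad <= 0.10 * length(rpe_depths),
             "flatten: >10% of A-scans have no identifiable RPE")
  for (loc in seq_len(n_loc)) {
    r <- rpe_depths[loc, ]
    if (anyNA(r)) {
      ok <- which(is.finite(r))
      rpe_depths[loc, ] <- stats::approx(ok, r[ok], xout = seq_along(r),
                                         rule = 2)$y
    }
  }
  rpe_px <- round(rpe_depths / volume$axial_scale)
  target <- round(stats::median(rpe_px))
  shift <- target - rpe_px  # positive: move content deeper
  out <- volume$data
  for (loc in seq_len(n_loc)) {
    rows <- (loc - 1L) * repeats + seq_len(repeats)
    for (i in seq_len(d[2])) {
      s <- shift[loc, i]
      if (s == 0L) next
      for (f in rows) {
        a <- out[f, i, ]
        if (s > 0L) {
          out[f, i, ] <- c(rep(a[1L], s), a[seq_len(d[3] - s)])
        } else {
          out[f, i, ] <- c(a[(1L - s):d[3]], rep(a[d[3]], -s))
        }
      }
    }
  }
  vol <- volume
  vol$data <- out
  attr(vol, "shift_px") <- shift
  attr(vol, "rpe_target_um") <- (target - 1L) * volume$axial_scale
  vol
}

#' Apply pseudorosette and optic nerve head exclusions to a profile
#'
#' The validity mask is ANDed with the ONH exclusion zone (total width
#' `2 * onh_halfwidth` centred on the ONH) and, optionally, with a rosette
#' mask or detected en-face spot footprints.  Values are untouched.
#'
#' @param profile a [thickness_profile()].
#' @param rosette_mask optional logical vector (TRUE = rosette present,
#'   excluded), aligned to the profile grid.
#' @param spots optional `spot_set` (from [detect_spots()]); profile
#'   positions within `footprint_margin * effective spot radius` of a spot
#'   centroid along the meridian (assumed at x = 0) are excluded.
#' @param onh_halfwidth half-width of the ONH exclusion (mm), default
#'   0.09 mm (0.18 mm total).
#' @param footprint_margin multiple of the spot radius used as footprint.
#' @export
exclude_regions <- function(profile, rosette_mask = NULL, spots = NULL,
                            onh_halfwidth = 0.09, footprint_margin = 1.5) {
  check_that(inherits(profile, "thickness_profile"),
             "profile must be a thickness_profile")
  mask <- profile$mask & abs(profile$position_mm) >= onh_halfwidth
  if (!is.null(rosette_mask)) {
    check_that(length(rosette_mask) == nrow(profile),
               "rosette_mask must align with the profile grid")
    mask <- mask & !rosette_mask
  }
  if (!is.null(spots) && nrow(spots)) {
    r_eff <- footprint_margin * sqrt(spots$area_mm2 / pi)
    for (k in seq_len(nrow(spots))) {
      if (abs(spots$x_mm[k]) > r_eff[k]) next
      mask <- mask & abs(profile$position_mm - spots$y_mm[k]) > r_eff[k]
    }
  }
  check_that(any(mask), "exclude_regions: all positions excluded")
  thickness_profile(profile$position_mm, profile$value_um, mask)
}

#' Montage overlapping thickness profile segments
#'
#' Segments acquired at different ONH offsets are shifted onto a common grid
#' (the spacing of the first segment); overlapping valid samples are
#' averaged.  Non-overlapping (disjoint) inputs are an error.
#'
#' @param segments list of [thickness_profile()] objects, positions relative
#'   to each segment's own scan centre.
#' @param onh_offsets numeric vector (mm): offset of each segment's centre
#'   from the ONH.
#' @export
montage_profiles <- function(segments, onh_offsets) {
  check_that(length(segments) >= 1L &&
               length(onh_offsets) == length(segments),
             "need one offset per segment")
  spacing <- stats::median(diff(segments[[1L]]$position_mm))
  shifted <- lapply(seq_along(segments), function(k) {
    s <- segments[[k]]
    data.frame(position_mm = s$position_mm + onh_offsets[k],
               value_um = s$value_um, mask = s$mask)
  })
  if (length(segments) > 1L) {
    iv <- t(vapply(shifted, function(s) range(s$position_mm), numeric(2)))
    ord <- order(iv[, 1])
    gaps <- iv[ord[-1], 1] - iv[ord[-nrow(iv)], 2]
    check_that(all(gaps <= spacing / 2),
               "montage_profiles: segments do not overlap")
  }
  lo <- min(vapply(shifted, function(s) min(s$position_mm), numeric(1)))
  hi <- max(vapply(shifted, function(s) max(s$position_mm), numeric(1)))
  grid <- seq(lo, hi + spacing / 2, by = spacing)
  acc <- num <- numeric(length(grid))
  for (s in shifted) {
    idx <- round((s$position_mm - lo) / spacing) + 1L
    keep <- s$mask & idx >= 1L & idx <= length(grid)
    acc[idx[keep]] <- acc[idx[keep]] + s$value_um[keep]
    num[idx[keep]] <- num[idx[keep]] + 1L
  }
  vals <- ifelse(num > 0, acc / pmax(num, 1), NA_real_)
  thickness_profile(grid, vals, num > 0)
}

#' Cohort mean and SD of thickness profiles
#'
#' With `per_eye = FALSE`, pools all valid data points of all profiles (the
#' convention for a single meridian display: mean and SD over all points in
#' the vertical profile, ONH zone excluded upstream).  With
#' `per_eye = TRUE`, first averages each eye's valid points, then summarises
#' across eyes (the convention for cohort comparisons).
#'
#' @param profiles list of [thickness_profile()] objects (one per eye).
#' @param per_eye logical, see above.
#' @param group_label cohort label.
#' @return object of class `cohort_summary`: `mean`, `sd`, `n` (eyes),
#'   `group_label`, and `eye_means` when `per_eye = TRUE`.
#' @export
profile_mean_sd <- function(profiles, per_eye = FALSE, group_label = "") {
  check_that(length(profiles) >= 1L, "need at least one profile")
  vals <- lapply(profiles, function(p) p$value_um[p$mask])
  check_that(any(lengths(vals) > 0), "no valid data points")
  if (per_eye) {
    em <- vapply(vals, function(v) if (length(v)) mean(v) else NA_real_,
                 numeric(1))
    em <- em[is.finite(em)]
    out <- list(mean = mean(em),
                sd = if (length(em) > 1L) stats::sd(em) else 0,
                n = length(em), group_label = group_label, eye_means = em)
  } else {
    allv <- unlist(vals)
    out <- list(mean = mean(allv),
                sd = if (length(allv) > 1L) stats::sd(allv) else 0,
                n = length(profiles), group_label = group_label)
  }
  structure(out, class = "cohort_summary")
}

#' Thickness fraction relative to a baseline cohort
#'
#' Normalises a cohort mean to the mean of the youngest age studied.
#'
#' @param group,baseline `cohort_summary` objects.
#' @return fraction (unitless).
#' @export
fraction_vs_baseline <- function(group, baseline) {
  check_that(inherits(group, "cohort_summary") &&
               inherits(baseline, "cohort_summary"),
             "arguments must be cohort_summary objects")
  check_that(baseline$mean > 0, "baseline mean must be > 0")
  group$mean / baseline$mean
}

#' Unpaired two-tailed t-test between two groups
#'
#' Welch's unequal-variance test by default; the pooled-variance test is
#' available with `var_equal = TRUE`.  Significance convention: p < 0.05.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param var_equal use the pooled-variance test.
#' @return list with `t`, `p`, `df`.
#' @export
compare_groups <- function(a, b, var_equal = FALSE) {
  check_that(length(a) >= 2L && length(b) >= 2L, "each group needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    # degenerate: t.test() refuses constant data
    if (mean(a) == mean(b)) return(list(t = 0, p = 1, df = NA_real_))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0, df = NA_real_))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), p = unname(ht$p.value),
       df = unname(ht$parameter))
}
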
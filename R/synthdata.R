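# Synthetic-data generators: layered-retina OCT phantoms with pseudorosettes,
# ERG amplitude cohorts on a log-linear decay, and human foveal ONL profiles.
# Every generator takes an explicit seed and returns exact ground truth.

DEFAULT_BANDS <- data.frame(
  band         = c("vri", "inner", "opl", "splus", "rpe", "choroid"),
  reflectivity = c(0.55, 0.40, 0.50, 0.45, 0.80, 0.50),
  width_um     = c(6, 12, 6, 6, 5, 10),
  stringsAsFactors = FALSE
)

#' Parameters for the layered-retina OCT phantom
#'
#' The phantom renders an axial reflectivity profile per A-scan as a sum of
#' Gaussian bands (vitreoretinal interface, inner retina, OPL peak, S+ band,
#' RPE, choroid) over a low baseline, with shallow negative dips pinning the
#' two ONL+ boundary troughs (the trough sclerad of the OPL peak and the
#' trough vitreal to the RPE band) at designed depths, so ground truth is
#' exact.  The RPE is the second hyperreflective band from the scleral side,
#' as required by the segmentation definition.  Band depths are derived from
#' the thickness geometry: RPE depth = interface depth + total thickness;
#' pre-RPE trough = RPE - `pre_rpe_gap`; OPL-side trough = pre-RPE trough -
#' ONL+ thickness.
#'
#' @param scan_mode `"linescan"` for a high-resolution meridian line scan
#'   (B-scans are repeat frames of the same vertical line through the ONH;
#'   LRP lateral positions run along the meridian, positive = superior) or
#'   `"raster"` for a square en-face raster over the field (B-scan index =
#'   vertical position, LRP index = horizontal position).
#' @param n_bscans number of stored B-scan frames.  For `"linescan"` this is
#'   `n_repeats` (repeat frames with independent noise); for `"raster"` it is
#'   the number of scan lines.
#' @param n_lrps_per_bscan A-scans per B-scan.
#' @param n_repeats repeat frames per B-scan location (linescan mode).
#' @param axial_px,axial_scale axial samples and scale (um/pixel).
#' @param field_diameter field of view (mm).  For linescan mode this is the
#'   meridian span covered by one scan.
#' @param vri_depth mean vitreoretinal-interface depth (um).
#' @param total_thickness_mean,total_thickness_sd total retinal thickness
#'   (interface to RPE peak) mean and smooth within-eye variation SD (um).
#' @param onl_thickness_mean,onl_thickness_sd ONL+ thickness mean and smooth
#'   within-eye variation SD (um).
#' @param pre_rpe_gap,opl_gap,splus_gap,choroid_gap band geometry (um): the
#'   pre-RPE trough sits `pre_rpe_gap` vitreal of the RPE peak, the OPL peak
#'   `opl_gap` vitreal of the OPL-side trough, the S+ band `splus_gap`
#'   vitreal of the pre-RPE trough, the choroidal band `choroid_gap` sclerad
#'   of the RPE.
#' @param bands data.frame with columns `band`, `reflectivity`, `width_um`
#'   for the six bands; the RPE reflectivity must exceed its neighbours.
#' @param baseline,dip_depth,dip_sigma background reflectivity, depth of the
#'   trough-pinning dips and their Gaussian sigma (um).
#' @param rpe_curvature_amplitude,rpe_curvature_period sinusoidal depth
#'   modulation of the whole retina (um / mm), emulating ocular curvature.
#' @param rosette_density_by_sector named numeric vector of pseudorosette
#'   densities (count per mm^2); names define the placement scheme
#'   (`superior`/`inferior` halves, the four quadrant names, or `all`).
#'   Defaults are the young-eye hemifield counts (44 superior, 73 inferior)
#'   divided by the hemifield sampling area.
#' @param rosette_count_by_sector optional named integer vector of exact
#'   planted counts per sector, overriding the Poisson draw.
#' @param rosette_radius,rosette_axial_semi,rosette_reflectivity lateral
#'   radius (um), axial semi-axis (um) and reflectivity of the
#'   hyperreflective ellipsoids.
#' @param onh_radius optic nerve head exclusion radius (mm).
#' @param noise_sd additive Gaussian reflectivity noise SD (a.u.).
#' @param seed integer RNG seed.
#' @return validated parameter object of class `oct_phantom_params`.
#' @export
oct_phantom_params <- function(scan_mode = c("linescan", "raster"),
                               n_bscans = NULL,
                               n_lrps_per_bscan = NULL,
                               n_repeats = 1L,
                               axial_px = 512L,
                               axial_scale = 1.6,
                               field_diameter = 1.5,
                               vri_depth = 48,
                               total_thickness_mean = 197.4,
                               total_thickness_sd = 0,
                               onl_thickness_mean = 66.4,
                               onl_thickness_sd = 0,
                               pre_rpe_gap = 18,
                               opl_gap = 20,
                               splus_gap = 18,
                               choroid_gap = 25,
                               bands = DEFAULT_BANDS,
                               baseline = 0.10,
                               dip_depth = 0.08,
                               dip_sigma = 6,
                               rpe_curvature_amplitude = 10,
                               rpe_curvature_period = 1.6,
                               rosette_density_by_sector = NULL,
                               rosette_count_by_sector = NULL,
                               rosette_radius = 25,
                               rosette_axial_semi = 28,
                               rosette_reflectivity = 0.85,
                               onh_radius = 0.09,
                               noise_sd = 0.02,
                               seed = 1L) {
  scan_mode <- match.arg(scan_mode)
  if (is.null(n_bscans)) n_bscans <- if (scan_mode == "linescan") n_repeats else 200L
  if (is.null(n_lrps_per_bscan)) n_lrps_per_bscan <- if (scan_mode == "linescan") 1000L else 200L
  if (is.null(rosette_density_by_sector)) {
    hemi_area <- pi * ((field_diameter / 2)^2 - onh_radius^2) / 2
    rosette_density_by_sector <- c(superior = 44 / hemi_area,
                                   inferior = 73 / hemi_area)
  }
  p <- list(
    scan_mode = scan_mode, n_bscans = as.integer(n_bscans),
    n_lrps_per_bscan = as.integer(n_lrps_per_bscan),
    n_repeats = as.integer(n_repeats),
    axial_px = as.integer(axial_px), axial_scale = axial_scale,
    field_diameter = field_diameter, vri_depth = vri_depth,
    total_thickness_mean = total_thickness_mean,
    total_thickness_sd = total_thickness_sd,
    onl_thickness_mean = onl_thickness_mean,
    onl_thickness_sd = onl_thickness_sd,
    pre_rpe_gap = pre_rpe_gap, opl_gap = opl_gap, splus_gap = splus_gap,
    choroid_gap = choroid_gap, bands = bands, baseline = baseline,
    dip_depth = dip_depth, dip_sigma = dip_sigma,
    rpe_curvature_amplitude = rpe_curvature_amplitude,
    rpe_curvature_period = rpe_curvature_period,
    rosette_density_by_sector = rosette_density_by_sector,
    rosette_count_by_sector = rosette_count_by_sector,
    rosette_radius = rosette_radius,
    rosette_axial_semi = rosette_axial_semi,
    rosette_reflectivity = rosette_reflectivity,
    onh_radius = onh_radius, noise_sd = noise_sd, seed = as.integer(seed)
  )
  class(p) <- "oct_phantom_params"
  validate_oct_phantom_params(p)
  p
}

validate_oct_phantom_params <- function(p) {
  check_that(p$n_bscans >= 1L && p$n_lrps_per_bscan >= 1L && p$axial_px >= 16L,
             "counts must be >= 1 (axial_px >= 16)")
  check_that(p$axial_scale > 0 && p$field_diameter > 0,
             "scales must be positive")
  check_that(p$noise_sd >= 0 && p$onl_thickness_sd >= 0 &&
               p$total_thickness_sd >= 0,
             "SDs must be >= 0")
  check_that(all(p$rosette_density_by_sector >= 0),
             "rosette densities must be >= 0")
  check_that(p$scan_mode != "linescan" || p$n_bscans %% p$n_repeats == 0L,
             "n_bscans must be a multiple of n_repeats")
  check_that(p$onl_thickness_mean > p$splus_gap + 10,
             "onl_thickness_mean must exceed splus_gap + 10 um so band ",
             "depths increase vitreal to sclerad")
  check_that(p$total_thickness_mean >
               p$onl_thickness_mean + p$pre_rpe_gap + p$opl_gap + 20,
             "total thickness too small for the configured band geometry")
  b <- p$bands
  check_that(identical(sort(b$band), sort(DEFAULT_BANDS$band)),
             "bands must contain exactly: ",
             paste(DEFAULT_BANDS$band, collapse = ", "))
  rpe_a <- b$reflectivity[b$band == "rpe"]
  nb <- b$reflectivity[b$band %in% c("splus", "choroid")]
  check_that(rpe_a > max(nb) + 0.05,
             "RPE reflectivity must exceed adjacent bands by > 0.05")
  depth_needed <- p$vri_depth + p$total_thickness_mean + p$choroid_gap + 40
  check_that(p$axial_px * p$axial_scale > depth_needed,
             "axial range too small: need > ", round(depth_needed), " um")
  invisible(p)
}

band_val <- function(p, band, what) p$bands[[what]][p$bands$band == band]

# Designed band depths (um) for A-scans with given onl, total and curvature
# vectors.  Returns a list of per-A-scan depth vectors.
phantom_depths <- function(p, onl, total, curv) {
  d_vri <- p$vri_depth + curv
  d_rpe <- p$vri_depth + total + curv
  t2 <- d_rpe - p$pre_rpe_gap
  t1 <- t2 - onl
  d_opl <- t1 - p$opl_gap
  d_splus <- t2 - p$splus_gap
  d_inner <- (d_vri + d_opl) / 2
  d_chor <- d_rpe + p$choroid_gap
  list(vri = d_vri, inner = d_inner, opl = d_opl, t1 = t1,
       splus = d_splus, t2 = t2, rpe = d_rpe, choroid = d_chor)
}

# Render a [axial_px x n_ascan] noise-free reflectivity matrix from depths.
render_profiles <- function(p, dep) {
  z <- (seq_len(p$axial_px) - 1) * p$axial_scale
  n <- length(dep$vri)
  M <- matrix(p$baseline, p$axial_px, n)
  for (bn in c("vri", "inner", "opl", "splus", "rpe", "choroid")) {
    A <- band_val(p, bn, "reflectivity")
    s <- band_val(p, bn, "width_um")
    M <- M + A * exp(-(outer(z, dep[[bn]], "-"))^2 / (2 * s^2))
  }
  for (tn in c("t1", "t2")) {
    M <- M - p$dip_depth * exp(-(outer(z, dep[[tn]], "-"))^2 /
                                 (2 * p$dip_sigma^2))
  }
  pmax(M, 0)
}

# Ground-truth boundary pixels from a rendered noise-free matrix: argmin/argmax
# within +-win pixels of the designed depth.  Returns 1-based pixel indices.
gt_extremum_px <- function(M, design_um, axial_scale, win = 10L,
                           minimum = TRUE) {
  n <- ncol(M)
  npx <- nrow(M)
  centre <- round(design_um / axial_scale) + 1L
  out <- integer(n)
  for (i in seq_len(n)) {
    lo <- max(1L, centre[i] - win); hi <- min(npx, centre[i] + win)
    seg <- M[lo:hi, i]
    out[i] <- lo - 1L + if (minimum) which.min(seg) else which.max(seg)
  }
  out
}

# Sector membership of en-face points (x nasal-positive, y superior-positive).
sector_of <- function(x, y, scheme = c("halves", "quadrants")) {
  scheme <- match.arg(scheme)
  if (scheme == "halves") {
    ifelse(y >= 0, "superior", "inferior")
  } else {
    ang <- atan2(y, x) * 180 / pi  # (-180, 180], 0 = nasal, 90 = superior
    ifelse(ang > 45 & ang <= 135, "superior",
           ifelse(ang > -135 & ang <= -45, "inferior",
                  ifelse(ang > -45 & ang <= 45, "nasal", "temporal")))
  }
}

sector_scheme_of <- function(sector_names) {
  if (all(sector_names %in% c("superior", "inferior")) ||
      identical(sector_names, "all")) "halves" else "quadrants"
}

# Draw rosette centroids: per-sector counts (Poisson unless exact counts are
# supplied), uniform positions within the sector annulus, rejecting centroid
# pairs closer than 2 * radius; bounded retries.
place_rosettes <- function(p) {
  dens <- p$rosette_density_by_sector
  sectors <- names(dens)
  check_that(!is.null(sectors) && all(nzchar(sectors)),
             "rosette_density_by_sector must be named")
  r_out <- p$field_diameter / 2 - p$rosette_radius / 1000
  r_in <- p$onh_radius + p$rosette_radius / 1000
  full_area <- pi * (r_out^2 - r_in^2)
  n_sec <- if (identical(sectors, "all")) 1L else
    if (all(sectors %in% c("superior", "inferior"))) 2L else 4L
  sec_area <- full_area / n_sec
  scheme <- sector_scheme_of(sectors)
  counts <- if (!is.null(p$rosette_count_by_sector)) {
    cnt <- p$rosette_count_by_sector
    check_that(setequal(names(cnt), sectors),
               "rosette_count_by_sector names must match densities")
    cnt[sectors]
  } else {
    stats::setNames(stats::rpois(length(dens), dens * sec_area), sectors)
  }
  xs <- ys <- numeric(0)
  labs <- character(0)
  min_sep <- 2 * p$rosette_radius / 1000
  for (s in sectors) {
    placed <- 0L
    tries <- 0L
    while (placed < counts[[s]]) {
      tries <- tries + 1L
      if (tries > 1000L * max(1L, counts[[s]])) {
        stop("rosette placement failed after bounded retries: density too ",
             "high for non-overlapping placement in sector '", s, "'")
      }
      x <- stats::runif(1, -r_out, r_out)
      y <- stats::runif(1, -r_out, r_out)
      rr <- sqrt(x^2 + y^2)
      if (rr < r_in || rr > r_out) next
      if (s != "all" && sector_of(x, y, scheme) != s) next
      if (length(xs) && any((xs - x)^2 + (ys - y)^2 < min_sep^2)) next
      xs <- c(xs, x); ys <- c(ys, y); labs <- c(labs, s)
      placed <- placed + 1L
    }
  }
  data.frame(x_mm = xs, y_mm = ys, sector = labs, stringsAsFactors = FALSE)
}

#' Generate a synthetic OCT volume with exact ground truth
#'
#' Renders the layered-retina phantom described in [oct_phantom_params()]:
#' Gaussian reflectivity bands at designed depths, a smooth RPE curvature
#' field shifting whole A-scans, hyperreflective pseudorosette ellipsoids
#' placed by a per-sector Poisson process with overlap rejection, and
#' additive Gaussian noise.  Ground truth (per-A-scan ONL+ and total
#' thickness on the rendered pixel grid, the continuous RPE depth field, and
#' the planted rosette centroids) is returned exactly.
#'
#' @param params an [oct_phantom_params()] object.
#' @return list with elements `volume` (class `oct_volume`: `data` array of
#'   shape `(n_bscans, n_lrps_per_bscan, axial_px)` plus scale/orientation
#'   metadata) and `ground_truth` (class `oct_ground_truth`).
#' @export
gen_oct_volume <- function(params) {
  p <- validate_oct_phantom_params(params)
  with_seed(p$seed, {
    if (p$scan_mode == "linescan") gen_oct_linescan(p) else gen_oct_raster(p)
  })
}

gen_oct_linescan <- function(p) {
  n <- p$n_lrps_per_bscan
  pos <- (seq_len(n) - (n + 1) / 2) * (p$field_diameter / n)  # mm, + = superior
  lateral_scale <- p$field_diameter / n
  onl <- p$onl_thickness_mean +
    smooth_field_1d(pos, p$onl_thickness_sd, knot_spacing = 0.3)
  total <- p$total_thickness_mean +
    smooth_field_1d(pos, p$total_thickness_sd, knot_spacing = 0.3)
  phase <- stats::runif(1, 0, 2 * pi)
  curv <- p$rpe_curvature_amplitude *
    cos(2 * pi * pos / p$rpe_curvature_period + phase)
  # clamp extreme tail draws to the geometric floor so band depths always
  # increase vitreal -> sclerad (affects only rare, thin-eye excursions)
  onl <- pmax(onl, p$splus_gap + 8)
  total <- pmax(total, onl + p$pre_rpe_gap + p$opl_gap + 12)
  dep <- phantom_depths(p, onl, total, curv)
  M0 <- render_profiles(p, dep)
  # ground truth on the rendered grid, before rosette overlay
  t1_px <- gt_extremum_px(M0, dep$t1, p$axial_scale, minimum = TRUE)
  t2_px <- gt_extremum_px(M0, dep$t2, p$axial_scale, minimum = TRUE)
  vri_px <- gt_extremum_px(M0, dep$vri, p$axial_scale, minimum = FALSE)
  rpe_px <- gt_extremum_px(M0, dep$rpe, p$axial_scale, minimum = FALSE)
  rosettes <- place_rosettes(p)
  r_mm <- p$rosette_radius / 1000
  rosette_mask <- rep(FALSE, n)
  if (nrow(rosettes)) {
    centre_depth <- (dep$t1 + dep$t2) / 2 - 10
    for (k in seq_len(nrow(rosettes))) {
      if (abs(rosettes$x_mm[k]) >= r_mm) next  # off the scanned meridian line
      hit <- which((pos - rosettes$y_mm[k])^2 + rosettes$x_mm[k]^2 < r_mm^2)
      for (i in hit) {
        rho2 <- ((pos[i] - rosettes$y_mm[k])^2 + rosettes$x_mm[k]^2) / r_mm^2
        h <- p$rosette_axial_semi * sqrt(max(0, 1 - rho2))
        zlo <- max(1L, floor((centre_depth[i] - h) / p$axial_scale) + 1L)
        zhi <- min(p$axial_px, ceiling((centre_depth[i] + h) / p$axial_scale) + 1L)
        if (zlo <= zhi) {
          M0[zlo:zhi, i] <- pmax(M0[zlo:zhi, i], p$rosette_reflectivity)
          rosette_mask[i] <- TRUE
        }
      }
    }
  }
  dat <- array(0, dim = c(p$n_bscans, n, p$axial_px))
  for (f in seq_len(p$n_bscans)) {
    noise <- if (p$noise_sd > 0)
      matrix(stats::rnorm(length(M0), 0, p$noise_sd), nrow(M0)) else 0
    dat[f, , ] <- t(M0 + noise)
  }
  vol <- new_oct_volume(dat, axial_scale = p$axial_scale,
                        lateral_scale = lateral_scale,
                        field_diameter = p$field_diameter,
                        scan_mode = "linescan", n_repeats = p$n_repeats,
                        seed = p$seed, params = p)
  gt <- structure(list(
    onl_plus_map = (t2_px - t1_px) * p$axial_scale,
    total_thickness_map = (rpe_px - vri_px) * p$axial_scale,
    rpe_depth_map = dep$rpe,
    opl_trough_map = (t1_px - 1) * p$axial_scale,
    pre_rpe_trough_map = (t2_px - 1) * p$axial_scale,
    rosette_centroids = rosettes,
    rosette_mask = rosette_mask,
    positions_mm = pos
  ), class = "oct_ground_truth")
  list(volume = vol, ground_truth = gt)
}

gen_oct_raster <- function(p) {
  ny <- p$n_bscans; nx <- p$n_lrps_per_bscan
  ypos <- ((ny + 1) / 2 - seq_len(ny)) * (p$field_diameter / ny)  # row 1 = top
  xpos <- (seq_len(nx) - (nx + 1) / 2) * (p$field_diameter / nx)
  onl <- p$onl_thickness_mean +
    smooth_field_2d(ypos, xpos, p$onl_thickness_sd, knot_spacing = 0.3)
  total <- p$total_thickness_mean +
    smooth_field_2d(ypos, xpos, p$total_thickness_sd, knot_spacing = 0.3)
  phase <- stats::runif(2, 0, 2 * pi)
  curv <- p$rpe_curvature_amplitude *
    outer(cos(2 * pi * ypos / p$rpe_curvature_period + phase[1]),
          cos(2 * pi * xpos / p$rpe_curvature_period + phase[2]))
  onl <- pmax(onl, p$splus_gap + 8)
  total <- pmax(total, onl + p$pre_rpe_gap + p$opl_gap + 12)
  rosettes <- place_rosettes(p)
  r_mm <- p$rosette_radius / 1000
  dat <- array(0, dim = c(ny, nx, p$axial_px))
  onl_map <- total_map <- rpe_map <- matrix(0, ny, nx)
  rosette_mask <- matrix(FALSE, ny, nx)
  for (iy in seq_len(ny)) {
    dep <- phantom_depths(p, onl[iy, ], total[iy, ], curv[iy, ])
    M <- render_profiles(p, dep)
    t1_px <- gt_extremum_px(M, dep$t1, p$axial_scale, minimum = TRUE)
    t2_px <- gt_extremum_px(M, dep$t2, p$axial_scale, minimum = TRUE)
    vri_px <- gt_extremum_px(M, dep$vri, p$axial_scale, minimum = FALSE)
    rpe_px <- gt_extremum_px(M, dep$rpe, p$axial_scale, minimum = FALSE)
    if (nrow(rosettes)) {
      centre_depth <- (dep$t1 + dep$t2) / 2 - 10
      near <- which(abs(rosettes$y_mm - ypos[iy]) < r_mm)
      for (k in near) {
        hit <- which((xpos - rosettes$x_mm[k])^2 +
                       (ypos[iy] - rosettes$y_mm[k])^2 < r_mm^2)
        for (i in hit) {
          rho2 <- ((xpos[i] - rosettes$x_mm[k])^2 +
                     (ypos[iy] - rosettes$y_mm[k])^2) / r_mm^2
          h <- p$rosette_axial_semi * sqrt(max(0, 1 - rho2))
          zlo <- max(1L, floor((centre_depth[i] - h) / p$axial_scale) + 1L)
          zhi <- min(p$axial_px,
                     ceiling((centre_depth[i] + h) / p$axial_scale) + 1L)
          if (zlo <= zhi) {
            M[zlo:zhi, i] <- pmax(M[zlo:zhi, i], p$rosette_reflectivity)
            rosette_mask[iy, i] <- TRUE
          }
        }
      }
    }
    if (p$noise_sd > 0)
      M <- M + matrix(stats::rnorm(length(M), 0, p$noise_sd), nrow(M))
    dat[iy, , ] <- t(M)
    onl_map[iy, ] <- (t2_px - t1_px) * p$axial_scale
    total_map[iy, ] <- (rpe_px - vri_px) * p$axial_scale
    rpe_map[iy, ] <- dep$rpe
  }
  vol <- new_oct_volume(dat, axial_scale = p$axial_scale,
                        lateral_scale = p$field_diameter / nx,
                        field_diameter = p$field_diameter,
                        scan_mode = "raster", n_repeats = 1L,
                        seed = p$seed, params = p)
  gt <- structure(list(
    onl_plus_map = onl_map, total_thickness_map = total_map,
    rpe_depth_map = rpe_map, rosette_centroids = rosettes,
    rosette_mask = rosette_mask, positions_y_mm = ypos, positions_x_mm = xpos
  ), class = "oct_ground_truth")
  list(volume = vol, ground_truth = gt)
}

#' Construct an OCT volume container
#'
#' @param data numeric array `(n_bscans, n_lrps, axial_px)`.
#' @param axial_scale um/pixel; `lateral_scale` mm/pixel along the LRP axis.
#' @param field_diameter mm; `scan_mode` `"linescan"` or `"raster"`.
#' @param n_repeats stored repeat frames per location (linescan).
#' @param seed,params provenance (optional).
#' @return object of class `oct_volume`.
#' @export
new_oct_volume <- function(data, axial_scale, lateral_scale, field_diameter,
                           scan_mode = "raster", n_repeats = 1L, seed = NULL,
                           params = NULL) {
  check_that(length(dim(data)) == 3L, "volume data must be a 3-D array")
  structure(list(
    data = data, axial_scale = axial_scale, lateral_scale = lateral_scale,
    field_diameter = field_diameter, scan_mode = scan_mode,
    n_repeats = as.integer(n_repeats),
    orientation = list(vertical = "superior_positive",
                       horizontal = "nasal_positive"),
    seed = seed, params = params
  ), class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<oct_volume> %s, %d b-scans x %d LRPs x %d axial px (%.2f um/px, %.4f mm/px)\n",
              x$scan_mode, d[1], d[2], d[3], x$axial_scale, x$lateral_scale))
  invisible(x)
}

#' Parameters for a synthetic ERG amplitude cohort
#'
#' Cone b-wave amplitudes decay exponentially with age; on log-linear axes the
#' decay is a straight line.  Amplitudes are generated as
#' `max(noise_floor, 10^(intercept_log + slope_log * age + eps))` with
#' `eps ~ N(0, scatter_sd^2)` (log-normal inter-animal scatter).  The default
#' line passes through the two printed endpoint cohort means, 139 uV at P31
#' and 22 uV at P83; default scatter is 0.2 log10 units and the default noise
#' floor 5 uV (responses near the system noise level are not meaningful).
#'
#' @param intercept_log log10 amplitude (uV) at age 0.
#' @param slope_log log10 uV per day; must be <= 0 (decay).
#' @param scatter_sd inter-animal scatter, log10 units.
#' @param noise_floor minimum reportable amplitude (uV).
#' @param ages vector of ages (days); `n_per_age` animals at each age.
#' @param stimulus `"UV"` or `"M"`.
#' @param seed integer RNG seed.
#' @export
erg_cohort_params <- function(intercept_log = NULL,
                              slope_log = (log10(22) - log10(139)) / 52,
                              scatter_sd = 0.2,
                              noise_floor = 5,
                              ages = seq(31, 83, by = 4),
                              n_per_age = 7L,
                              stimulus = c("UV", "M"),
                              seed = 1L) {
  if (is.null(intercept_log)) intercept_log <- log10(139) - slope_log * 31
  stimulus <- match.arg(stimulus)
  check_that(length(ages) >= 1L, "ages must be non-empty")
  check_that(slope_log <= 0, "slope_log must be <= 0 for a decay")
  check_that(scatter_sd >= 0 && noise_floor >= 0,
             "scatter_sd and noise_floor must be >= 0")
  check_that(all(ages > 0) && n_per_age >= 1L, "ages and n_per_age positive")
  structure(list(intercept_log = intercept_log, slope_log = slope_log,
                 scatter_sd = scatter_sd, noise_floor = noise_floor,
                 ages = ages, n_per_age = as.integer(n_per_age),
                 stimulus = stimulus, seed = as.integer(seed)),
            class = "erg_cohort_params")
}

#' Generate a synthetic ERG b-wave amplitude cohort
#'
#' @param params an [erg_cohort_params()] object.
#' @return data.frame with columns `animal_id`, `age_days`, `stimulus`,
#'   `amplitude_uV`.
#' @export
gen_erg_cohort <- function(params) {
  p <- params
  check_that(inherits(p, "erg_cohort_params"), "params must come from erg_cohort_params()")
  with_seed(p$seed, {
    age <- rep(p$ages, each = p$n_per_age)
    eps <- if (p$scatter_sd > 0) stats::rnorm(length(age), 0, p$scatter_sd) else 0
    amp <- pmax(p$noise_floor,
                10^(p$intercept_log + p$slope_log * age + eps))
    data.frame(
      animal_id = sprintf("a%03d", seq_along(age)),
      age_days = age,
      stimulus = p$stimulus,
      amplitude_uV = amp,
      stringsAsFactors = FALSE
    )
  })
}

#' Parameters for a synthetic human foveal ONL profile
#'
#' Emulates the residual foveal island seen in severe early-onset retinal
#' blindness: a central ONL peak on a zero (disease-like) or positive
#' (normal-like) baseline.  For a Gaussian island on a zero baseline the
#' analytic half-maximum width is `2 * sqrt(2 * log(2)) * shape_scale`.
#'
#' @param peak_onl peak ONL thickness at the foveal centre (um).
#' @param island_shape `"gaussian"`, `"triangular"` or `"table"`.
#' @param shape_scale Gaussian sigma or triangle half-base (mm).
#' @param baseline_onl thickness far from the island (um).
#' @param sample_spacing,extent sampling grid: eccentricities
#'   `seq(-extent, extent, by = sample_spacing)` (mm).
#' @param noise_sd additive measurement noise (um).
#' @param meridian `"horizontal"` or `"vertical"` (recorded, not interpreted).
#' @param table_profile for `island_shape = "table"`: data.frame with columns
#'   `eccentricity_mm`, `onl_um` sampled directly (noise still added).
#' @param seed integer RNG seed.
#' @export
foveal_phantom_params <- function(peak_onl = 100,
                                  island_shape = c("gaussian", "triangular", "table"),
                                  shape_scale = 0.25,
                                  baseline_onl = 0,
                                  sample_spacing = 0.05,
                                  extent = 1.5,
                                  noise_sd = 2,
                                  meridian = c("horizontal", "vertical"),
                                  table_profile = NULL,
                                  seed = 1L) {
  island_shape <- match.arg(island_shape)
  meridian <- match.arg(meridian)
  check_that(peak_onl >= 0 && baseline_onl >= 0,
             "peak and baseline thickness must be >= 0")
  check_that(extent > 0 && sample_spacing > 0, "extent and spacing must be > 0")
  check_that(noise_sd >= 0, "noise_sd must be >= 0")
  if (island_shape == "table")
    check_that(is.data.frame(table_profile) &&
                 all(c("eccentricity_mm", "onl_um") %in% names(table_profile)),
               "table shape requires table_profile(eccentricity_mm, onl_um)")
  structure(list(peak_onl = peak_onl, island_shape = island_shape,
                 shape_scale = shape_scale, baseline_onl = baseline_onl,
                 sample_spacing = sample_spacing, extent = extent,
                 noise_sd = noise_sd, meridian = meridian,
                 table_profile = table_profile, seed = as.integer(seed)),
            class = "foveal_phantom_params")
}

#' Generate a synthetic foveal ONL thickness profile
#'
#' @param params a [foveal_phantom_params()] object.
#' @return a `foveal_profile`: data.frame `(eccentricity_mm, onl_um)` with
#'   attributes `meridian` and `ground_truth` (list with the analytic
#'   half-maximum width `width_half_max_mm`, `NA` when undefined).
#' @export
gen_foveal_profile <- function(params) {
  p <- params
  check_that(inherits(p, "foveal_phantom_params"),
             "params must come from foveal_phantom_params()")
  with_seed(p$seed, {
    x <- seq(-p$extent, p$extent, by = p$sample_spacing)
    A <- p$peak_onl - p$baseline_onl
    clean <- switch(p$island_shape,
      gaussian = p$baseline_onl + A * exp(-x^2 / (2 * p$shape_scale^2)),
      triangular = p$baseline_onl + A * pmax(0, 1 - abs(x) / p$shape_scale),
      table = stats::approx(p$table_profile$eccentricity_mm,
                            p$table_profile$onl_um, xout = x, rule = 2)$y
    )
    onl <- pmax(0, clean + if (p$noise_sd > 0)
      stats::rnorm(length(x), 0, p$noise_sd) else 0)
    gt_width <- analytic_half_max_width(p)
    prof <- data.frame(eccentricity_mm = x, onl_um = onl)
    attr(prof, "meridian") <- p$meridian
    attr(prof, "ground_truth") <- list(width_half_max_mm = gt_width,
                                       peak_onl = p$peak_onl,
                                       baseline_onl = p$baseline_onl)
    class(prof) <- c("foveal_profile", "data.frame")
    prof
  })
}

# Closed-form half-max width of the configured island (NA when the half-max
# level does not cross the flanks, e.g. high baseline or no island).
analytic_half_max_width <- function(p) {
  A <- p$peak_onl - p$baseline_onl
  if (p$island_shape == "table" || A <= 0) return(NA_real_)
  half <- p$peak_onl / 2
  if (half <= p$baseline_onl) return(NA_real_)
  if (p$island_shape == "gaussian") {
    2 * p$shape_scale * sqrt(2 * log(A / (half - p$baseline_onl)))
  } else {
    2 * p$shape_scale * (1 - (half - p$baseline_onl) / A)
  }
}
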
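# Integrated en-face backscatter maps, hyperreflective spot (pseudorosette)
# detection, and sector count/density statistics.

#' Integrate OCT backscatter over an axial slab
#'
#' Produces an en-face map by summing reflectivity over axial pixels whose
#' depth lies in `[z_top, z_bottom)`.  The slab boundaries are chosen to
#' envelope all rosettes; the volume should be flattened to the RPE first so
#' a fixed slab tracks the same anatomy across the field.
#'
#' @param volume a flattened raster-mode `oct_volume`.
#' @param z_top,z_bottom slab boundaries in um (`z_top < z_bottom`).
#' @return object of class `enface_map`: `intensity` matrix (rows = vertical
#'   position, row 1 = superior edge; columns = horizontal, nasal positive),
#'   lateral scales (mm/px), the slab, and the ONH centre (pixels).
#' @export
integrate_slab <- function(volume, z_top, z_bottom) {
  check_that(inherits(volume, "oct_volume"), "volume must be an oct_volume")
  check_that(z_top < z_bottom, "slab must satisfy z_top < z_bottom")
  d <- dim(volume$data)
  z <- (seq_len(d[3]) - 1) * volume$axial_scale
  sel <- which(z >= z_top & z < z_bottom)
  check_that(length(sel) > 0L, "empty slab: no axial pixels in [z_top, z_bottom)")
  intensity <- apply(volume$data[, , sel, drop = FALSE], c(1, 2), sum)
  structure(list(
    intensity = intensity,
    lateral_scale_x = volume$lateral_scale,
    lateral_scale_y = volume$field_diameter / d[1],
    slab = c(z_top = z_top, z_bottom = z_bottom),
    onh_center_px = c(row = (d[1] + 1) / 2, col = (d[2] + 1) / 2),
    field_diameter = volume$field_diameter
  ), class = "enface_map")
}

# Otsu's threshold on a numeric vector (256-bin histogram, maximises
# between-class variance).
otsu_threshold <- function(v, nbins = 256L) {
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) <= 0) return(NA_real_)
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(v, br, all.inside = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-(nbins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, nbins)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  mids[which.max(sigma_b)]
}

# 4-connected component labelling of a logical matrix; returns an integer
# label matrix (0 = background).
label_components <- function(bw) {
  nr <- nrow(bw); nc <- ncol(bw)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  stack <- integer(sum(bw))
  for (start in which(bw)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    sp <- 1L
    stack[1L] <- start
    lab[start] <- cur
    while (sp > 0L) {
      id <- stack[sp]; sp <- sp - 1L
      r <- ((id - 1L) %% nr) + 1L
      cc <- ((id - 1L) %/% nr) + 1L
      for (nb in c(if (r > 1L) id - 1L, if (r < nr) id + 1L,
                   if (cc > 1L) id - nr, if (cc < nc) id + nr)) {
        if (bw[nb] && lab[nb] == 0L) {
          lab[nb] <- cur
          sp <- sp + 1L
          stack[sp] <- nb
        }
      }
    }
  }
  lab
}

#' Detect hyperreflective spots (pseudorosettes) in an en-face map
#'
#' Thresholds the map (Otsu by default), labels 4-connected components,
#' filters by minimum area, and reports centroids in mm relative to the ONH.
#' Pixels inside the ONH exclusion disk are removed before thresholding.
#'
#' @param map an [integrate_slab()] result.
#' @param threshold_mode `"otsu"` or a numeric absolute threshold.  The Otsu
#'   threshold is floored at `median + mad_k * MAD` of the map: Otsu assumes
#'   a bimodal histogram and would otherwise split pure background noise on
#'   a spotless map.
#' @param min_area minimum spot area in mm^2.
#' @param mad_k robust background floor multiplier.
#' @param onh_radius ONH exclusion disk radius (mm).
#' @return object of class `spot_set`: data.frame `(x_mm, y_mm, area_mm2)`
#'   with attribute `field_radius`.  A constant (degenerate) map yields an
#'   empty set with a warning.
#' @export
detect_spots <- function(map, threshold_mode = "otsu", min_area = 4e-4,
                         mad_k = 6, onh_radius = 0.09) {
  check_that(inherits(map, "enface_map"), "map must be an enface_map")
  img <- map$intensity
  check_that(all(is.finite(img)), "map intensities must be finite")
  nr <- nrow(img); nc <- ncol(img)
  y_mm <- (map$onh_center_px["row"] - seq_len(nr)) * map$lateral_scale_y
  x_mm <- (seq_len(nc) - map$onh_center_px["col"]) * map$lateral_scale_x
  inside_onh <- outer(y_mm^2, x_mm^2, "+") < onh_radius^2
  empty <- function() {
    s <- data.frame(x_mm = numeric(0), y_mm = numeric(0),
                    area_mm2 = numeric(0))
    attr(s, "field_radius") <- map$field_diameter / 2
    class(s) <- c("spot_set", "data.frame")
    s
  }
  vals <- img[!inside_onh]
  if (length(vals) == 0L || diff(range(vals)) <= 0) {
    warning("detect_spots: constant en-face map; returning empty spot set")
    return(empty())
  }
  thr <- if (identical(threshold_mode, "otsu")) {
    max(otsu_threshold(vals),
        stats::median(vals) + mad_k * stats::mad(vals))
  } else as.numeric(threshold_mode)
  bw <- img > thr & !inside_onh
  if (!any(bw)) return(empty())
  lab <- label_components(bw)
  px_area <- map$lateral_scale_x * map$lateral_scale_y
  n <- max(lab)
  xs <- ys <- areas <- numeric(n)
  keep <- logical(n)
  for (k in seq_len(n)) {
    idx <- which(lab == k)
    a <- length(idx) * px_area
    if (a < min_area) next
    r <- ((idx - 1L) %% nr) + 1L
    cc <- ((idx - 1L) %/% nr) + 1L
    # intensity-weighted centroid
    w <- img[idx] - thr
    xs[k] <- sum(x_mm[cc] * w) / sum(w)
    ys[k] <- sum(y_mm[r] * w) / sum(w)
    areas[k] <- a
    keep[k] <- TRUE
  }
  s <- data.frame(x_mm = xs[keep], y_mm = ys[keep], area_mm2 = areas[keep])
  attr(s, "field_radius") <- map$field_diameter / 2
  class(s) <- c("spot_set", "data.frame")
  s
}

#' Sector counts and densities of detected spots
#'
#' Spots are assigned to sectors by centroid angle (superior wedge centred on
#' +90 degrees, inferior on -90, nasal on 0, temporal on 180 for the
#' quadrant scheme; the halves scheme splits on the horizontal midline).
#' Density is count per sector area, the sector's share of the annulus
#' between the ONH exclusion disk and the field radius.
#'
#' @param spots a `spot_set`.
#' @param field_radius sampled field radius (mm); defaults to the spot set's
#'   recorded field radius.
#' @param scheme `"halves"` (superior/inferior) or `"quadrants"`.
#' @param onh_radius ONH disk radius (mm) removed from the sector area.
#' @return data.frame `(sector, count, density_per_mm2)` covering every
#'   sector of the scheme (zero counts included).
#' @export
sector_stats <- function(spots, field_radius = NULL,
                         scheme = c("halves", "quadrants"),
                         onh_radius = 0.09) {
  scheme <- match.arg(scheme)
  if (is.null(field_radius)) field_radius <- attr(spots, "field_radius")
  check_that(is.numeric(field_radius) && field_radius > 0,
             "field_radius required")
  if (nrow(spots)) {
    rr <- sqrt(spots$x_mm^2 + spots$y_mm^2)
    check_that(all(rr <= field_radius + 1e-9),
               "spot centroid outside the sampled field")
  }
  sectors <- if (scheme == "halves") c("superior", "inferior")
             else c("superior", "inferior", "nasal", "temporal")
  area <- pi * (field_radius^2 - onh_radius^2) / length(sectors)
  lab <- if (nrow(spots)) sector_of(spots$x_mm, spots$y_mm, scheme)
         else character(0)
  counts <- vapply(sectors, function(s) sum(lab == s), integer(1))
  data.frame(sector = sectors, count = as.integer(counts),
             density_per_mm2 = counts / area, row.names = NULL,
             stringsAsFactors = FALSE)
}
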
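# Volume and table I/O.
#
# Volumes are stored as multi-page TIFF (one page per B-scan, 64-bit IEEE
# float samples, uncompressed, little-endian, one strip per page) with a
# JSON sidecar carrying scales, orientation, seed and generator parameters.
# The TIFF writer/reader is self-contained (no TIFF library in the
# dependency set) and restricted to this dialect; it produces standard
# baseline TIFF readable by common scientific readers.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, spp = 277L,
               rows_per_strip = 278L, strip_bytes = 279L,
               sample_format = 339L)

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

tiff_entry <- function(tag, type, count, value) {
  # type 3 = SHORT, 4 = LONG; value left-justified in the 4-byte field
  val <- if (type == 3L) c(u16(value), as.raw(c(0, 0))) else u32(value)
  c(u16(tag), u16(type), u32(count), val)
}

#' Write an OCT volume as multi-page TIFF plus JSON sidecar
#'
#' @param volume an `oct_volume`.
#' @param path output TIFF path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  check_that(inherits(volume, "oct_volume"), "volume must be an oct_volume")
  d <- dim(volume$data)
  n_pages <- d[1]; w <- d[2]; h <- d[3]
  page_bytes <- 8L * w * h
  data_start <- 8L
  ifd_start <- data_start + n_pages * page_bytes
  ifd_size <- 2L + 10L * 12L + 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(c(0x49, 0x49)), u16(42L), u32(ifd_start)), con)
  for (pg in seq_len(n_pages)) {
    # page is an axial-by-lateral image: rows = axial depth, cols = LRPs
    img <- t(volume$data[pg, , ])       # [h x w], row-major per TIFF row
    writeBin(as.numeric(t(img)), con, size = 8, endian = "little")
  }
  for (pg in seq_len(n_pages)) {
    strip_off <- data_start + (pg - 1L) * page_bytes
    next_ifd <- if (pg < n_pages) ifd_start + pg * ifd_size else 0L
    ifd <- c(
      u16(10L),
      tiff_entry(TIFF_TAGS["width"], 4L, 1L, w),
      tiff_entry(TIFF_TAGS["length"], 4L, 1L, h),
      tiff_entry(TIFF_TAGS["bits"], 3L, 1L, 64L),
      tiff_entry(TIFF_TAGS["compression"], 3L, 1L, 1L),
      tiff_entry(TIFF_TAGS["photometric"], 3L, 1L, 1L),
      tiff_entry(TIFF_TAGS["strip_offsets"], 4L, 1L, strip_off),
      tiff_entry(TIFF_TAGS["spp"], 3L, 1L, 1L),
      tiff_entry(TIFF_TAGS["rows_per_strip"], 4L, 1L, h),
      tiff_entry(TIFF_TAGS["strip_bytes"], 4L, 1L, page_bytes),
      tiff_entry(TIFF_TAGS["sample_format"], 3L, 1L, 3L),
      u32(next_ifd)
    )
    writeBin(ifd, con)
  }
  sidecar <- list(
    format = "retnathist-oct-1",
    n_bscans = n_pages, n_lrps = w, axial_px = h,
    axial_scale_um = volume$axial_scale,
    lateral_scale_mm = volume$lateral_scale,
    field_diameter_mm = volume$field_diameter,
    scan_mode = volume$scan_mode, n_repeats = volume$n_repeats,
    orientation = volume$orientation, seed = volume$seed
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

read_u16 <- function(con) readBin(con, integer(), size = 2, signed = FALSE,
                                  endian = "little")
read_u32 <- function(con) readBin(con, integer(), size = 4, endian = "little")

#' Read an OCT volume written by [write_volume()]
#'
#' @param path TIFF path; `<path>.json` sidecar must exist.
#' @return an `oct_volume`.
#' @export
read_volume <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop("missing sidecar ", sidecar_path, "; required metadata keys: ",
         "axial_scale_um, lateral_scale_mm, field_diameter_mm, scan_mode, ",
         "n_repeats, orientation, seed")
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, raw(), 2)
  check_that(identical(magic, as.raw(c(0x49, 0x49))),
             "not a little-endian TIFF")
  check_that(read_u16(con) == 42L, "bad TIFF magic")
  ifd_off <- read_u32(con)
  pages <- list()
  while (ifd_off != 0L) {
    seek(con, ifd_off)
    n_entries <- read_u16(con)
    tags <- list()
    for (k in seq_len(n_entries)) {
      tag <- read_u16(con); type <- read_u16(con); count <- read_u32(con)
      val <- if (type == 3L) {
        v <- read_u16(con); read_u16(con); v
      } else read_u32(con)
      tags[[as.character(tag)]] <- val
    }
    ifd_off <- read_u32(con)
    w <- tags[["256"]]; h <- tags[["257"]]
    check_that(tags[["258"]] == 64L && tags[["339"]] == 3L &&
                 tags[["259"]] == 1L,
               "unsupported TIFF dialect (need uncompressed float64)")
    seek(con, tags[["273"]])
    vals <- readBin(con, numeric(), n = w * h, size = 8, endian = "little")
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, byrow = TRUE)
  }
  n_pages <- length(pages)
  check_that(n_pages == meta$n_bscans,
             "TIFF page count (", n_pages, ") disagrees with sidecar (",
             meta$n_bscans, ")")
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  dat <- array(0, dim = c(n_pages, w, h))
  for (pg in seq_len(n_pages)) dat[pg, , ] <- t(pages[[pg]])
  new_oct_volume(dat, axial_scale = meta$axial_scale_um,
                 lateral_scale = meta$lateral_scale_mm,
                 field_diameter = meta$field_diameter_mm,
                 scan_mode = meta$scan_mode, n_repeats = meta$n_repeats,
                 seed = meta$seed)
}

#' Write/read CSV tables with header validation
#'
#' @param x data.frame to write.
#' @param path CSV path.
#' @export
write_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @param expected_cols required column names, in order; a mismatch is a
#'   schema error.
#' @export
read_table <- function(path, expected_cols = NULL) {
  check_that(file.exists(path), "no such file: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(expected_cols)) {
    check_that(identical(names(x)[seq_along(expected_cols)], expected_cols),
               "schema error in ", path, ": expected columns [",
               paste(expected_cols, collapse = ","), "], found [",
               paste(names(x), collapse = ","), "]")
  }
  x
}

#' Write phantom ground truth (JSON summary + centroid CSV)
#'
#' @param gt an `oct_ground_truth`.
#' @param prefix output path prefix: writes `<prefix>_ground_truth.json` and
#'   `<prefix>_rosettes.csv`.
#' @export
write_ground_truth <- function(gt, prefix) {
  js <- list(
    onl_plus_um = as.vector(gt$onl_plus_map),
    total_thickness_um = as.vector(gt$total_thickness_map),
    rpe_depth_um = as.vector(gt$rpe_depth_map),
    n_rosettes = nrow(gt$rosette_centroids)
  )
  jsonlite::write_json(js, paste0(prefix, "_ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write_table(gt$rosette_centroids, paste0(prefix, "_rosettes.csv"))
  invisible(prefix)
}
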
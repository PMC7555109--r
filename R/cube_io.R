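#' Multispectral reflectance cube
#'
#' Container for a calibrated multispectral image: a `height x width x bands`
#' array of reflectance values in `[0, 1]`, the band wavelengths in nm
#' (strictly increasing), and the isotropic pixel size in micrometers.
#'
#' @param pixels numeric array, `height x width x n_bands`.
#' @param wavelengths numeric vector of band wavelengths (nm), strictly
#'   increasing, length equal to the third dimension of `pixels`.
#' @param pixel_size pixel edge length in micrometers per pixel.
#' @return an object of class `msi_cube`.
#' @export
msi_cube <- function(pixels, wavelengths, pixel_size) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3)
  if (length(wavelengths) != dim(pixels)[3])
    stop("number of bands (", dim(pixels)[3], ") does not match the ",
         length(wavelengths), " wavelengths supplied")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (!all(is.finite(pixels)))
    stop("cube contains non-finite reflectance values")
  stopifnot(is.numeric(pixel_size), pixel_size > 0)
  structure(list(pixels = pixels,
                 wavelengths = as.numeric(wavelengths),
                 pixel_size = as.numeric(pixel_size)),
            class = "msi_cube")
}

#' @export
print.msi_cube <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<msi_cube> %d x %d px, %d bands (%g-%g nm), %g um/px\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              x$pixel_size))
  invisible(x)
}

#' @export
dim.msi_cube <- function(x) dim(x$pixels)

# ---- minimal float32 TIFF writing -----------------------------------------
# tiff::writeTIFF only stores integer samples; reflectance cubes need IEEE
# float32 pages so that write/read round-trips are bit-exact. This writes
# uncompressed little-endian multi-page TIFFs (SampleFormat = 3) that
# tiff::readTIFF reads back exactly.
write_float32_tiff <- function(pages, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  n <- length(pages)
  strip_size <- H * W * 4L
  n_tags <- 10L
  ifd_size <- 2L + n_tags * 12L + 4L
  data_off <- 8L + (seq_len(n) - 1L) * strip_size
  ifd0 <- 8L + n * strip_size
  ifd_off <- ifd0 + (seq_len(n) - 1L) * ifd_size
  # header
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd0, con, size = 4, endian = "little")
  # strips (row-major)
  for (p in pages)
    writeBin(as.vector(t(p)), con, size = 4, endian = "little")
  tag <- function(id, type, value) {
    writeBin(as.integer(id), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(1L, con, size = 4, endian = "little")
    if (type == 3L) { # SHORT, inline low bytes
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (i in seq_len(n)) {
    writeBin(n_tags, con, size = 2, endian = "little")
    tag(256L, 4L, W)                 # ImageWidth
    tag(257L, 4L, H)                 # ImageLength
    tag(258L, 3L, 32L)               # BitsPerSample
    tag(259L, 3L, 1L)                # Compression: none
    tag(262L, 3L, 1L)                # Photometric: BlackIsZero
    tag(273L, 4L, data_off[i])       # StripOffsets
    tag(277L, 3L, 1L)                # SamplesPerPixel
    tag(278L, 4L, H)                 # RowsPerStrip
    tag(279L, 4L, strip_size)        # StripByteCounts
    tag(339L, 3L, 3L)                # SampleFormat: IEEE float
    writeBin(if (i < n) ifd_off[i + 1L] else 0L, con, size = 4,
             endian = "little")
  }
  invisible(path)
}

#' Write a multispectral cube to a multi-page TIFF with JSON sidecar
#'
#' One 32-bit float page per band, in ascending wavelength order, plus a
#' `<path>.json` sidecar holding the wavelengths (nm) and pixel size
#' (um/px). Values are stored in IEEE single precision, so doubles are
#' rounded to the nearest float32 on write; a written file round-trips
#' bit-exactly through [read_cube()].
#'
#' @param cube an [msi_cube()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "msi_cube"))
  d <- dim(cube$pixels)
  pages <- lapply(seq_len(d[3]), function(b)
    snap_float32(cube$pixels[, , b]))
  write_float32_tiff(pages, path)
  jsonlite::write_json(
    list(wavelengths_nm = cube$wavelengths, pixel_size_um = cube$pixel_size),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read a multispectral cube written by [write_cube()]
#'
#' @param path TIFF path; the `<path>.json` sidecar must exist.
#' @return an [msi_cube()].
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("missing sidecar '", sp,
         "' (wavelengths_nm and pixel_size_um metadata)")
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  wl <- as.numeric(meta$wavelengths_nm)
  if (length(pages) != length(wl))
    stop("TIFF has ", length(pages), " pages but sidecar lists ",
         length(wl), " wavelengths")
  px <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (b in seq_along(pages)) px[, , b] <- pages[[b]]
  msi_cube(px, wl, as.numeric(meta$pixel_size_um))
}

#' Write / read a binary mask as a single-page TIFF
#'
#' @param mask logical matrix.
#' @param path TIFF path.
#' @return `write_mask` returns `path` invisibly; `read_mask` a logical
#'   matrix.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  tiff::writeTIFF(matrix(as.numeric(mask), nrow(mask)), path,
                  bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0.5
}

#' White/dark reference calibration set
#'
#' @param white,dark [msi_cube()]s (or plain arrays) of the white and dark
#'   reference acquisitions, same shape as the cubes to be corrected.
#' @return an object of class `calibration_set`.
#' @export
calibration_set <- function(white, dark) {
  w <- if (inherits(white, "msi_cube")) white$pixels else white
  d <- if (inherits(dark, "msi_cube")) dark$pixels else dark
  stopifnot(identical(dim(w), dim(d)))
  structure(list(white = w, dark = d), class = "calibration_set")
}

#' Convert raw counts to reflectance using white/dark references
#'
#' Standard flat-field correction `R = (raw - dark) / (white - dark)`,
#' clipped to `[0, 1]`. With `white = 1` and `dark = 0` the operation is the
#' identity on already-calibrated data.
#'
#' @param raw an [msi_cube()] of raw counts.
#' @param cal a [calibration_set()] with the same dimensions.
#' @return a calibrated [msi_cube()].
#' @export
reflectance_correct <- function(raw, cal) {
  stopifnot(inherits(raw, "msi_cube"), inherits(cal, "calibration_set"))
  if (!identical(dim(raw$pixels), dim(cal$white)))
    stop("calibration cubes do not match the raw cube dimensions")
  denom <- cal$white - cal$dark
  if (any(denom <= 0))
    stop("white reference does not exceed dark reference everywhere; ",
         "reflectance is undefined (division by zero)")
  r <- (raw$pixels - cal$dark) / denom
  r[r < 0] <- 0
  r[r > 1] <- 1
  msi_cube(r, raw$wavelengths, raw$pixel_size)
}

#' Area-normalized mean spectrum of a cube
#'
#' Spatial mean reflectance per band (optionally restricted to a mask),
#' rescaled so the area under the curve equals 1.
#'
#' @param cube an [msi_cube()].
#' @param mask optional logical matrix selecting the pixels to average.
#' @return data frame with columns `wavelength_nm` and
#'   `normalized_reflectance` (summing to 1).
#' @export
mean_spectrum <- function(cube, mask = NULL) {
  stopifnot(inherits(cube, "msi_cube"))
  d <- dim(cube$pixels)
  if (is.null(mask)) {
    s <- apply(cube$pixels, 3, mean)
  } else {
    stopifnot(is.logical(mask), all(dim(mask) == d[1:2]))
    if (!any(mask)) stop("mask selects no pixels")
    s <- apply(cube$pixels, 3, function(b) mean(b[mask]))
  }
  tot <- sum(s)
  if (tot <= 0) stop("cube has zero total reflectance; cannot normalize")
  data.frame(wavelength_nm = cube$wavelengths,
             normalized_reflectance = s / tot)
}

#' Write a mean spectrum as a two-column CSV
#'
#' @param spectrum data frame from [mean_spectrum()].
#' @param path output CSV path.
#' @export
write_spectrum <- function(spectrum, path) {
  write.csv(spectrum, path, row.names = FALSE)
  invisible(path)
}
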
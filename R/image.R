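#' Two-channel reporter image
#'
#' Container for one field of view of a dual-fluorophore mitophagy reporter:
#' a red (mCherry) and a green (GFP) intensity raster of identical size, plus
#' the pixel calibration. Intensities are arbitrary detector units (DN).
#'
#' @param red,green numeric matrices (rows = y, columns = x) of finite,
#'   non-negative intensities; identical dimensions.
#' @param pixel_size_um positive scalar, micrometres per pixel side.
#' @param name image identifier used in result tables and file names.
#' @return An object of class `two_channel_image` (a list with elements
#'   `red`, `green`, `pixel_size_um`, `name`).
#' @examples
#' img <- two_channel_image(matrix(1, 8, 8), matrix(1, 8, 8))
#' dim(img$red)
#' @export
two_channel_image <- function(red, green, pixel_size_um = 1, name = "image") {
  red <- as.matrix(red)
  green <- as.matrix(green)
  red <- matrix(as.numeric(red), nrow(red), ncol(red))     # drop attributes
  green <- matrix(as.numeric(green), nrow(green), ncol(green))
  if (!identical(dim(red), dim(green)))
    stop("red and green channels have different dimensions")
  if (!all(is.finite(red)) || !all(is.finite(green)))
    stop("channel intensities must be finite")
  if (any(red < 0) || any(green < 0))
    stop("channel intensities must be non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a positive scalar")
  structure(list(red = red, green = green,
                 pixel_size_um = as.numeric(pixel_size_um),
                 name = as.character(name)[1]),
            class = "two_channel_image")
}

#' @export
print.two_channel_image <- function(x, ...) {
  cat(sprintf("<two_channel_image> '%s': %d x %d px, %.4g um/px\n",
              x$name, nrow(x$red), ncol(x$red), x$pixel_size_um))
  cat(sprintf("  red:   mean %.4g  max %.4g\n", mean(x$red), max(x$red)))
  cat(sprintf("  green: mean %.4g  max %.4g\n", mean(x$green), max(x$green)))
  invisible(x)
}

# parse an ImageJ-style TIFF description ("key=value" per line) into a list
parse_imagej_description <- function(desc) {
  if (is.null(desc) || !nzchar(desc)) return(list())
  lines <- strsplit(desc, "\n", fixed = TRUE)[[1]]
  kv <- strsplit(lines, "=", fixed = TRUE)
  kv <- kv[vapply(kv, length, 1L) == 2]
  out <- lapply(kv, `[`, 2)
  names(out) <- vapply(kv, `[`, "", 1)
  out
}

# micrometres per pixel from readTIFF attributes; NA when absent
pixel_size_from_info <- function(info) {
  xres <- attr(info, "x.resolution")
  if (is.null(xres) || !is.numeric(xres) || xres <= 0) return(NA_real_)
  unit <- attr(info, "resolution.unit")
  desc <- parse_imagej_description(attr(info, "description"))
  ij_unit <- if (!is.null(desc$unit)) desc$unit else ""
  if (ij_unit %in% c("micron", "um", "\u00b5m", "\u03bcm")) return(1 / xres)
  if (identical(unit, "cm")) return(10000 / xres)
  if (identical(unit, "inch")) return(25400 / xres)
  # unitless resolution: ImageJ convention is pixels per calibration unit,
  # which for fluorescence data is almost always microns
  1 / xres
}

#' Read a multi-channel TIFF as a two-channel image
#'
#' Accepts interleaved multi-page TIFFs, ImageJ hyperstacks (the `channels=`
#' entry of the ImageJ description names the channel axis) and single-page
#' multi-sample TIFFs. Channel indices are 1-based, matching the channel
#' numbering shown in FIJI; the user must say which channel is mCherry (red)
#' and which is GFP (green).
#'
#' @param path TIFF file path.
#' @param red_channel,green_channel 1-based channel indices (distinct).
#' @param pixel_size_um optional calibration override; when `NULL` the TIFF
#'   resolution metadata is used, falling back to 1 with a warning.
#' @param name image identifier; defaults to the file base name.
#' @return A [two_channel_image()].
#' @export
read_image <- function(path, red_channel, green_channel,
                       pixel_size_um = NULL, name = NULL) {
  if (!file.exists(path)) stop("image file not found: ", path)
  red_channel <- as.integer(red_channel)
  green_channel <- as.integer(green_channel)
  if (red_channel == green_channel)
    stop("red and green channel indices must be distinct")
  slices <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE),
    error = function(e) # float-sample TIFFs reject as.is; values are raw
      tiff::readTIFF(path, all = TRUE, info = TRUE))
  if (!is.list(slices)) slices <- list(slices)
  channels <- list()
  if (length(slices) == 1 && length(dim(slices[[1]])) == 3) {
    a <- slices[[1]]
    for (i in seq_len(dim(a)[3])) channels[[i]] <- a[, , i]
  } else {
    n_ch <- length(slices)
    desc <- parse_imagej_description(attr(slices[[1]], "description"))
    if (!is.null(desc$channels)) {
      n_ch <- min(as.integer(desc$channels), length(slices))
    }
    channels <- lapply(slices[seq_len(n_ch)], function(s) {
      if (length(dim(s)) == 3) s[, , 1] else s
    })
  }
  if (length(channels) < 2)
    stop("image has fewer than 2 channels")
  if (red_channel < 1 || red_channel > length(channels) ||
      green_channel < 1 || green_channel > length(channels))
    stop("channel index out of range (image has ", length(channels),
         " channels)")
  if (is.null(pixel_size_um)) {
    pixel_size_um <- pixel_size_from_info(slices[[1]])
    if (is.na(pixel_size_um)) {
      warning("no pixel calibration in TIFF metadata; assuming 1 \u03bcm/pixel")
      pixel_size_um <- 1
    }
  }
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  two_channel_image(channels[[red_channel]], channels[[green_channel]],
                    pixel_size_um = pixel_size_um, name = name)
}

## ---- calibrated baseline-TIFF writer -------------------------------------
## tiff::writeTIFF cannot emit resolution or description tags, so calibrated
## output (and the synthetic suite) is written here as plain uncompressed
## little-endian baseline TIFF: one grayscale strip per page, ImageJ-style
## description on the first page, X/YResolution in pixels per micron.

tiff_tag <- function(id, type, count, value) {
  # returns a 12-byte raw tag entry; `value` is inline (scalar) or an offset
  con <- rawConnection(raw(0), "w")
  on.exit(close(con))
  writeBin(as.integer(id), con, size = 2, endian = "little")
  writeBin(as.integer(type), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  if (type == 3 && count == 1) { # SHORT inline, padded
    writeBin(as.integer(value), con, size = 2, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  } else {
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  rawConnectionValue(con)
}

pixels_raw <- function(mat, dtype) {
  # row-major pixel stream for one page
  v <- as.vector(t(mat))
  con <- rawConnection(raw(0), "w")
  on.exit(close(con))
  if (dtype == "float32") {
    writeBin(as.numeric(v), con, size = 4, endian = "little")
  } else if (dtype == "uint16") {
    writeBin(as.integer(round(v)), con, size = 2, endian = "little")
  } else if (dtype == "uint8") {
    writeBin(as.integer(round(v)), con, size = 1, endian = "little")
  } else stop("unsupported dtype: ", dtype)
  rawConnectionValue(con)
}

#' Write matrices as a calibrated grayscale TIFF
#'
#' Writes one page per matrix as uncompressed baseline TIFF with pixel
#' calibration (X/YResolution in pixels per micron) and an ImageJ-style
#' description declaring the pages as channels, so FIJI opens the file as a
#' composite hyperstack.
#'
#' @param pages a matrix or list of matrices (identical dimensions).
#' @param path output file.
#' @param pixel_size_um micrometres per pixel side.
#' @param dtype `"uint16"`, `"float32"` or `"uint8"`; `"auto"` picks uint16
#'   for integer-valued data within 16-bit range, float32 otherwise.
#' @return `path`, invisibly.
#' @export
write_calibrated_tiff <- function(pages, path, pixel_size_um = 1,
                                  dtype = "auto") {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1)
  dims <- lapply(pages, dim)
  if (length(unique(dims)) != 1) stop("pages differ in size")
  h <- dims[[1]][1]; w <- dims[[1]][2]
  if (dtype == "auto") {
    vals <- unlist(lapply(pages, range))
    allint <- all(vapply(pages, function(p) all(p == round(p)), TRUE))
    dtype <- if (allint && max(vals) < 65536 && min(vals) >= 0)
      "uint16" else "float32"
  }
  bps <- c(uint8 = 8L, uint16 = 16L, float32 = 32L)[[dtype]]
  sfmt <- if (dtype == "float32") 3L else 1L
  bytespp <- bps / 8L
  n <- length(pages)

  desc <- sprintf(
    "ImageJ=1.52p\nimages=%d\nchannels=%d\nhyperstack=true\nmode=composite\nunit=micron\n",
    n, n)
  desc_count <- nchar(desc) + 1L            # ASCII count includes one NUL
  desc_raw <- c(charToRaw(desc), as.raw(0))
  if (length(desc_raw) %% 2 == 1) desc_raw <- c(desc_raw, as.raw(0))

  res_num <- round(1e6 / pixel_size_um)  # pixels per micron as rational
  res_den <- 1e6

  page_bytes <- h * w * bytespp
  data_off <- 8 + (seq_len(n) - 1) * page_bytes
  desc_off <- 8 + n * page_bytes
  xres_off <- desc_off + length(desc_raw)
  yres_off <- xres_off + 8
  ifd0_off <- yres_off + 8
  n_tags <- c(14L, rep(13L, n - 1))  # description on first page only
  ifd_size <- 2 + 12 * n_tags + 4
  ifd_off <- ifd0_off + cumsum(c(0, ifd_size[-n]))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd0_off), con, size = 4, endian = "little")
  for (p in pages) writeBin(pixels_raw(p, dtype), con)
  writeBin(desc_raw, con)
  for (off in c(xres_off, yres_off)) {
    writeBin(as.integer(res_num), con, size = 4, endian = "little")
    writeBin(as.integer(res_den), con, size = 4, endian = "little")
  }
  for (i in seq_len(n)) {
    tags <- list(
      tiff_tag(256, 3, 1, w),
      tiff_tag(257, 3, 1, h),
      tiff_tag(258, 3, 1, bps),
      tiff_tag(259, 3, 1, 1),          # uncompressed
      tiff_tag(262, 3, 1, 1))          # BlackIsZero
    if (i == 1)
      tags <- c(tags, list(tiff_tag(270, 2, desc_count, desc_off)))
    tags <- c(tags, list(
      tiff_tag(273, 4, 1, data_off[i]),
      tiff_tag(277, 3, 1, 1),
      tiff_tag(278, 3, 1, h),
      tiff_tag(279, 4, 1, page_bytes),
      tiff_tag(282, 5, 1, xres_off),
      tiff_tag(283, 5, 1, yres_off),
      tiff_tag(296, 3, 1, 1),          # unit carried by description instead
      tiff_tag(339, 3, 1, sfmt)))
    writeBin(length(tags), con, size = 2, endian = "little")
    for (tg in tags) writeBin(tg, con)
    nxt <- if (i < n) as.integer(ifd_off[i + 1]) else 0L
    writeBin(nxt, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Write a two-channel image as a calibrated TIFF
#'
#' @param image a [two_channel_image()]; channel 1 of the file is red,
#'   channel 2 green, unless `channel_order` swaps them.
#' @param path output file.
#' @param channel_order `c("red", "green")` by default.
#' @inheritParams write_calibrated_tiff
#' @return `path`, invisibly.
#' @export
write_two_channel_tiff <- function(image, path,
                                   channel_order = c("red", "green"),
                                   dtype = "auto") {
  stopifnot(inherits(image, "two_channel_image"))
  channel_order <- match.arg(channel_order, c("red", "green"), several.ok = TRUE)
  pages <- lapply(channel_order, function(ch) image[[ch]])
  write_calibrated_tiff(pages, path, pixel_size_um = image$pixel_size_um,
                        dtype = dtype)
}
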
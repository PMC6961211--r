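#' Region-of-interest sets
#'
#' A `roi_set` is an ordered collection of named regions delimiting cells or
#' tissue regions within one image. Each member is either a polygon (vertex
#' coordinates in pixel units, origin at the top-left corner of pixel (0,0)),
#' an oval (axis-aligned ellipse given by its bounding box), or a binary mask
#' raster. Polygons come from FIJI freehand/polygon selections; masks from
#' label-mask rasters.
#'
#' @param rois list of ROI objects as produced by [polygon_roi()] or
#'   [mask_roi()].
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(rois) {
  stopifnot(is.list(rois))
  labels <- vapply(rois, function(r) r$label, "")
  if (anyDuplicated(labels))
    stop("ROI labels must be unique within a set")
  structure(list(rois = rois), class = "roi_set")
}

#' @export
length.roi_set <- function(x) length(x$rois)

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROI(s): %s\n", length(x),
              paste(vapply(x$rois, function(r)
                sprintf("%s[%s]", r$label, r$type), ""), collapse = ", ")))
  invisible(x)
}

#' @rdname roi_set
#' @param vertices n x 2 matrix of (x, y) polygon vertices, n >= 3.
#' @param label ROI name.
#' @param type `"polygon"` or `"oval"` (ellipse inscribed in the vertex
#'   bounding box).
#' @export
polygon_roi <- function(vertices, label = "ROI", type = "polygon") {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3)
    stop("a polygon ROI needs an n x 2 vertex matrix with n >= 3")
  type <- match.arg(type, c("polygon", "oval"))
  structure(list(label = as.character(label), type = type,
                 vertices = vertices), class = "mq_roi")
}

#' @rdname roi_set
#' @param mask logical matrix, `TRUE` inside the region (>= 1 true pixel).
#' @export
mask_roi <- function(mask, label = "ROI") {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!any(mask)) stop("a mask ROI needs at least one true pixel")
  structure(list(label = as.character(label), type = "mask", mask = mask),
            class = "mq_roi")
}

# even-odd point-in-polygon, vectorised over query points
point_in_polygon_eo <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    denom <- vy[j] - vy[i]
    if (denom != 0) {
      crosses <- ((vy[i] > py) != (vy[j] > py)) &
        (px < (vx[j] - vx[i]) * (py - vy[i]) / denom + vx[i])
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  inside
}

polygon_area <- function(vx, vy) { # shoelace, absolute
  n <- length(vx)
  j <- c(n, seq_len(n - 1))
  abs(sum(vx[j] * vy - vx * vy[j])) / 2
}

#' Rasterize one ROI to a binary raster
#'
#' Polygon membership uses the even-odd rule evaluated at pixel centres
#' (x + 0.5, y + 0.5 in the ROI coordinate frame); vertices outside the image
#' are clipped by rasterization. Oval ROIs rasterize the inscribed ellipse of
#' their bounding box; mask ROIs are returned unchanged.
#'
#' @param roi an ROI ([polygon_roi()] / [mask_roi()] or a `roi_set` member).
#' @param image_shape integer `(height, width)` of the target raster.
#' @return Logical matrix `height x width`, `TRUE` inside the ROI.
#' @export
rasterize_roi <- function(roi, image_shape) {
  h <- as.integer(image_shape[1]); w <- as.integer(image_shape[2])
  if (roi$type == "mask") {
    if (!identical(dim(roi$mask), c(h, w)))
      stop("mask ROI dimensions do not match image shape")
    return(roi$mask)
  }
  vx <- roi$vertices[, 1]; vy <- roi$vertices[, 2]
  if (min(vx) >= w || max(vx) <= 0 || min(vy) >= h || max(vy) <= 0)
    stop("ROI outside image bounds")
  out <- matrix(FALSE, h, w)
  x0 <- max(0L, floor(min(vx))); x1 <- min(w - 1L, ceiling(max(vx)))
  y0 <- max(0L, floor(min(vy))); y1 <- min(h - 1L, ceiling(max(vy)))
  xs <- x0:x1; ys <- y0:y1
  px <- rep(xs, each = length(ys)) + 0.5
  py <- rep(ys, times = length(xs)) + 0.5
  inside <- if (roi$type == "oval") {
    cx <- (min(vx) + max(vx)) / 2; cy <- (min(vy) + max(vy)) / 2
    a <- (max(vx) - min(vx)) / 2; b <- (max(vy) - min(vy)) / 2
    ((px - cx) / a)^2 + ((py - cy) / b)^2 <= 1
  } else {
    point_in_polygon_eo(px, py, vx, vy)
  }
  out[cbind(rep(ys, times = length(xs)) + 1L,
            rep(xs, each = length(ys)) + 1L)] <- inside
  if (!any(out)) {
    if (roi$type == "polygon" && polygon_area(vx, vy) == 0)
      warning("degenerate (zero-area) polygon ROI '", roi$label,
              "' rasterizes to 0 pixels")
    else
      warning("ROI '", roi$label, "' rasterizes to 0 pixels")
  }
  out
}

## ---- ImageJ .roi binary format -------------------------------------------

ij_roi_types <- c("polygon" = 0L, "rect" = 1L, "oval" = 2L, "line" = 3L,
                  "freeline" = 4L, "polyline" = 5L, "noRoi" = 6L,
                  "freehand" = 7L, "traced" = 8L, "angle" = 9L, "point" = 10L)

read_u16be <- function(raw, off) as.integer(raw[off + 1]) * 256L +
  as.integer(raw[off + 2])
read_s16be <- function(raw, off) {
  v <- read_u16be(raw, off)
  if (v >= 32768L) v - 65536L else v
}

# Parse one ImageJ .roi blob into an ROI object.
decode_imagej_roi <- function(bytes, label) {
  if (length(bytes) < 64 || rawToChar(bytes[1:4]) != "Iout")
    stop("not an ImageJ ROI file")
  type_code <- as.integer(bytes[7])
  type_name <- names(ij_roi_types)[match(type_code, ij_roi_types)]
  if (is.na(type_name)) type_name <- as.character(type_code)
  top <- read_s16be(bytes, 8); left <- read_s16be(bytes, 10)
  bottom <- read_s16be(bytes, 12); right <- read_s16be(bytes, 14)
  n <- read_u16be(bytes, 16)
  options <- read_u16be(bytes, 50)
  if (type_code %in% c(1L, 2L)) { # rectangle / oval from bounding box
    verts <- cbind(c(left, right, right, left), c(top, top, bottom, bottom))
    return(polygon_roi(verts, label,
                       type = if (type_code == 2L) "oval" else "polygon"))
  }
  if (!type_code %in% c(0L, 7L, 8L))
    stop("unsupported ROI type: ", type_name)
  if (n < 3) stop("polygon ROI with fewer than 3 vertices")
  base <- 64L
  xs <- vapply(seq_len(n) - 1L,
               function(i) read_s16be(bytes, base + 2L * i), 0L) + left
  ys <- vapply(seq_len(n) - 1L,
               function(i) read_s16be(bytes, base + 2L * (n + i)), 0L) + top
  if (bitwAnd(options, 128L) != 0L &&
      length(bytes) >= base + 4L * n + 8L * n) {
    # SUB_PIXEL_RESOLUTION: float coordinates follow the integer block
    fcon <- rawConnection(bytes[(base + 4L * n + 1L):length(bytes)])
    fx <- readBin(fcon, "numeric", n = n, size = 4, endian = "big")
    fy <- readBin(fcon, "numeric", n = n, size = 4, endian = "big")
    close(fcon)
    if (all(is.finite(fx)) && all(is.finite(fy))) { xs <- fx; ys <- fy }
  }
  polygon_roi(cbind(xs, ys), label)
}

encode_imagej_roi <- function(roi) {
  if (roi$type == "mask")
    stop("mask ROIs cannot be written as ImageJ .roi files")
  vx <- roi$vertices[, 1]; vy <- roi$vertices[, 2]
  left <- floor(min(vx)); top <- floor(min(vy))
  n <- length(vx)
  con <- rawConnection(raw(0), "w")
  on.exit(close(con))
  writeBin(charToRaw("Iout"), con)
  writeBin(227L, con, size = 2, endian = "big")            # version
  type_code <- if (roi$type == "oval") 2L else 0L
  writeBin(as.integer(c(type_code, 0L)), con, size = 1)
  writeBin(as.integer(c(top, left, ceiling(max(vy)), ceiling(max(vx)))),
           con, size = 2, endian = "big")
  writeBin(if (roi$type == "oval") 0L else as.integer(n), con,
           size = 2, endian = "big")
  writeBin(raw(46), con)                                    # bytes 18..63
  if (type_code == 0L) {
    writeBin(as.integer(round(vx - left)), con, size = 2, endian = "big")
    writeBin(as.integer(round(vy - top)), con, size = 2, endian = "big")
  }
  rawConnectionValue(con)
}

## ---- stored (uncompressed) ZIP container ---------------------------------
## utils::zip needs an external `zip` binary; this writes the minimal stored
## format that ImageJ and utils::unzip both read.

write_u16 <- function(con, x) writeBin(as.integer(x), con, size = 2,
                                       endian = "little")
write_u32 <- function(con, x) {
  x <- as.numeric(x)
  writeBin(as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
                    (x %/% 16777216) %% 256)), con)
}

write_zip_stored <- function(entries, path) { # entries: named list of raw
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- numeric(length(entries))
  pos <- 0
  crcs <- numeric(length(entries))
  for (i in seq_along(entries)) {
    nm <- charToRaw(names(entries)[i]); dat <- entries[[i]]
    crcs[i] <- crc32_cpp(dat)
    offsets[i] <- pos
    write_u32(con, 0x04034b50); write_u16(con, 20); write_u16(con, 0)
    write_u16(con, 0); write_u16(con, 0); write_u16(con, 0x21)
    write_u32(con, crcs[i]); write_u32(con, length(dat))
    write_u32(con, length(dat)); write_u16(con, length(nm)); write_u16(con, 0)
    writeBin(nm, con); writeBin(dat, con)
    pos <- pos + 30 + length(nm) + length(dat)
  }
  cd_start <- pos
  for (i in seq_along(entries)) {
    nm <- charToRaw(names(entries)[i]); dat <- entries[[i]]
    write_u32(con, 0x02014b50); write_u16(con, 20); write_u16(con, 20)
    write_u16(con, 0); write_u16(con, 0); write_u16(con, 0)
    write_u16(con, 0x21); write_u32(con, crcs[i]); write_u32(con, length(dat))
    write_u32(con, length(dat)); write_u16(con, length(nm))
    write_u16(con, 0); write_u16(con, 0); write_u16(con, 0); write_u16(con, 0)
    write_u32(con, 0); write_u32(con, offsets[i])
    writeBin(nm, con)
    pos <- pos + 46 + length(nm)
  }
  write_u32(con, 0x06054b50); write_u16(con, 0); write_u16(con, 0)
  write_u16(con, length(entries)); write_u16(con, length(entries))
  write_u32(con, pos - cd_start); write_u32(con, cd_start); write_u16(con, 0)
  invisible(path)
}

## ---- public ROI I/O -------------------------------------------------------

#' Read ROIs from an ImageJ ROI file, a zip of ROIs, or a label mask
#'
#' `.roi` files and `.zip` containers follow the ImageJ ROI format
#' (polygon, freehand, traced, rectangle and oval selections are supported;
#' line and point types are rejected). TIFF/PNG rasters are interpreted as
#' label masks: each distinct non-zero value becomes one mask ROI, labelled
#' by its value.
#'
#' @param path `.roi`, `.zip`, `.tif(f)` or `.png` file.
#' @param image_shape optional `(height, width)`; required for consistency
#'   checks against mask rasters, unused for polygon files.
#' @return A [roi_set()] in file order.
#' @export
read_rois <- function(path, image_shape = NULL) {
  if (!file.exists(path)) stop("ROI file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "roi") {
    bytes <- readBin(path, "raw", file.size(path))
    label <- tools::file_path_sans_ext(basename(path))
    return(roi_set(list(decode_imagej_roi(bytes, label))))
  }
  if (ext == "zip") {
    listing <- utils::unzip(path, list = TRUE, unzip = "internal")
    names_in_order <- listing$Name[grepl("\\.roi$", listing$Name,
                                         ignore.case = TRUE)]
    if (length(names_in_order) == 0)
      stop("empty ROI container: ", path)
    exdir <- tempfile("rois")
    utils::unzip(path, exdir = exdir, unzip = "internal")
    rois <- lapply(names_in_order, function(nm) {
      f <- file.path(exdir, nm)
      decode_imagej_roi(readBin(f, "raw", file.size(f)),
                        tools::file_path_sans_ext(basename(nm)))
    })
    return(roi_set(rois))
  }
  if (ext %in% c("tif", "tiff", "png")) {
    lab <- if (ext == "png") {
      m <- png::readPNG(path)
      if (length(dim(m)) == 3) m <- m[, , 1]
      round(m * 255)
    } else {
      m <- tiff::readTIFF(path, as.is = TRUE)
      if (length(dim(m)) == 3) m <- m[, , 1]
      m
    }
    if (!is.null(image_shape) &&
        !identical(dim(lab), as.integer(image_shape)))
      stop("label mask dimensions do not match image shape")
    vals <- sort(unique(as.vector(lab)))
    vals <- vals[vals != 0]
    if (length(vals) == 0) stop("empty ROI container: label mask is all zero")
    return(roi_set(lapply(vals, function(v)
      mask_roi(lab == v, label = as.character(v)))))
  }
  stop("unsupported ROI container type: .", ext)
}

#' Write polygon ROIs as ImageJ .roi / .zip
#'
#' @param rois a [roi_set()] of polygon/oval ROIs.
#' @param path output path; `.roi` (single ROI only) or `.zip`.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "roi") {
    if (length(rois) != 1)
      stop("a .roi file holds exactly one ROI; use .zip for several")
    writeBin(encode_imagej_roi(rois$rois[[1]]), path)
    return(invisible(path))
  }
  if (ext != "zip") stop("ROI output path must end in .roi or .zip")
  entries <- lapply(rois$rois, encode_imagej_roi)
  names(entries) <- vapply(rois$rois, function(r) paste0(r$label, ".roi"), "")
  write_zip_stored(entries, path)
  invisible(path)
}
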
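#' Detection parameters
#'
#' The three user thresholds of the method plus the channel assignment.
#'
#' @param smooth_radius median-filter radius in pixels (>= 0). The kernel is
#'   the ImageJ circular neighbourhood (offsets with dx^2+dy^2 <= r^2+1);
#'   radius 1 is the full 3x3 window and the usual choice for widefield data.
#' @param ratio_thresh prominence ("noise tolerance") used to detect peaks in
#'   the mCherry/GFP ratio image; dimensionless ratio units, > 0. Typical
#'   working values 0.4-0.6 around the default 0.5.
#' @param red_stddev_offset `k` in the adaptive red threshold
#'   `mean(red) + k * sd(red)` computed over the whole smoothed red channel;
#'   may be negative. Raising `k` suppresses dim false-positive peaks.
#' @param red_channel,green_channel 1-based channel indices in the source
#'   TIFF.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(smooth_radius = 1, ratio_thresh = 0.5,
                             red_stddev_offset = 0,
                             red_channel = 1, green_channel = 2) {
  if (!is.numeric(smooth_radius) || smooth_radius < 0)
    stop("smooth_radius must be >= 0")
  if (!is.numeric(ratio_thresh) || ratio_thresh <= 0)
    stop("ratio_thresh must be > 0")
  if (!is.numeric(red_stddev_offset) || !is.finite(red_stddev_offset))
    stop("red_stddev_offset must be a finite scalar")
  structure(list(smooth_radius = as.numeric(smooth_radius),
                 ratio_thresh = as.numeric(ratio_thresh),
                 red_stddev_offset = as.numeric(red_stddev_offset),
                 red_channel = as.integer(red_channel),
                 green_channel = as.integer(green_channel)),
            class = "detection_params")
}

#' @export
print.detection_params <- function(x, ...) {
  cat(sprintf(paste0("<detection_params> smooth_radius=%g ratio_thresh=%g ",
                     "red_stddev_offset=%g channels(red=%d, green=%d)\n"),
              x$smooth_radius, x$ratio_thresh, x$red_stddev_offset,
              x$red_channel, x$green_channel))
  invisible(x)
}

#' Median smoothing with the ImageJ circular kernel
#'
#' Each pixel is replaced by the median of the circular neighbourhood
#' `{(dx, dy): dx^2 + dy^2 <= radius^2 + 1}` (so radius 1 is the full 3x3
#' window and radius 2 covers 21 pixels). Borders are handled by edge
#' replication; radius 0 returns the input unchanged.
#'
#' @param x numeric matrix.
#' @param radius neighbourhood radius in pixels, >= 0.
#' @return Smoothed matrix of the same dimensions.
#' @export
median_smooth <- function(x, radius) {
  if (!is.numeric(radius) || length(radius) != 1 || radius < 0)
    stop("radius must be a non-negative scalar")
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  median_filter_cpp(x, radius)
}

#' Number of offsets in the circular median kernel
#' @param radius kernel radius in pixels.
#' @return Integer count of `(dx, dy)` offsets with `dx^2+dy^2 <= radius^2+1`.
#' @export
median_kernel_size <- function(radius) kernel_size_cpp(radius)

#' Pixel-wise mCherry/GFP ratio image
#'
#' Both channels are median-smoothed first, then divided pixel by pixel.
#' Outside lysosomes red and green reporter intensities are similar, so the
#' ratio sits near 1; GFP quenching inside mitolysosomes raises it. Pixels
#' where smoothed green is 0 but red is positive get a large finite sentinel
#' (max finite ratio in the image + 2 * `ratio_thresh`, recomputed per
#' image) so they out-prominence every genuine peak while keeping the raster
#' finite; pixels where both channels are 0 get ratio 0.
#'
#' @param image a [two_channel_image()].
#' @param smooth_radius median-filter radius applied to both channels.
#' @param ratio_thresh prominence the caller will use on this raster; only
#'   sets the margin of the division-by-zero sentinel.
#' @return Numeric matrix of finite ratio values.
#' @export
compute_ratio <- function(image, smooth_radius = 1, ratio_thresh = 0.5) {
  stopifnot(inherits(image, "two_channel_image"))
  red <- median_smooth(image$red, smooth_radius)
  green <- median_smooth(image$green, smooth_radius)
  ratio <- red / green
  zero_both <- green == 0 & red == 0
  zero_green <- green == 0 & red > 0
  ratio[zero_both] <- 0
  if (any(zero_green)) {
    finite_max <- suppressWarnings(max(ratio[is.finite(ratio)], 0))
    ratio[zero_green] <- finite_max + 2 * ratio_thresh
  }
  ratio
}

#' Adaptive red-intensity threshold
#'
#' `mean(red) + k * sd(red)` with statistics over the entire raster and the
#' population (divide-by-N) standard deviation, matching ImageJ image
#' statistics. Used to reject ratio peaks that sit in dim background.
#'
#' @param red numeric matrix (the smoothed red channel).
#' @param k standard-deviation offset, may be negative.
#' @return Scalar threshold in intensity units.
#' @export
compute_red_threshold <- function(red, k = 0) {
  v <- as.vector(red)
  if (length(v) == 0) stop("empty raster")
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))
  mu + k * sigma
}

#' Find intensity maxima by topographic prominence
#'
#' ImageJ "Find Maxima" semantics under 8-connectivity: a local maximum is
#' reported iff every path from it to any strictly higher pixel drops below
#' its value minus `prominence` (its topographic prominence exceeds
#' `prominence`). Connected equal-valued plateaus count as one candidate and
#' equal-valued maxima connected within tolerance are merged into a single
#' peak; the reported pixel is the lexicographically smallest (y, x) plateau
#' member. A constant image has no maxima; border pixels are eligible.
#'
#' @param x numeric matrix.
#' @param prominence positive noise tolerance.
#' @return data.frame with 0-based `x` (column), `y` (row) and `value`
#'   columns, ordered by (y, x).
#' @export
find_maxima <- function(x, prominence) {
  if (!is.numeric(prominence) || length(prominence) != 1 || prominence <= 0)
    stop("prominence must be a positive scalar")
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  m <- find_maxima_cpp(x, prominence)
  data.frame(x = m[, 1], y = m[, 2],
             value = x[cbind(m[, 2] + 1L, m[, 1] + 1L)])
}

#' Filter peaks by minimum red intensity
#'
#' Keeps peaks whose (smoothed) red-channel intensity at the peak pixel is at
#' least the threshold, excluding spurious high-ratio pixels in low-intensity
#' background regions.
#'
#' @param peaks data.frame from [find_maxima()] (0-based `x`, `y`).
#' @param red numeric matrix, the smoothed red channel.
#' @param red_threshold_value scalar from [compute_red_threshold()].
#' @return The surviving rows of `peaks`.
#' @export
filter_peaks <- function(peaks, red, red_threshold_value) {
  if (nrow(peaks) == 0) return(peaks)
  keep <- red[cbind(peaks$y + 1L, peaks$x + 1L)] >= red_threshold_value
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the binary mitophagy mask
#'
#' For each accepted peak the 8-connected region of pixels with ratio within
#' `prominence` of the peak value ("maxima within tolerance") is flooded;
#' the union over peaks is then intersected with the set of pixels whose red
#' intensity meets the adaptive threshold. Mitolysosome areas are measured on
#' this mask.
#'
#' @param ratio ratio raster from [compute_ratio()].
#' @param peaks accepted peaks from [filter_peaks()].
#' @param prominence the noise tolerance used for detection.
#' @param red smoothed red channel (or `NULL` to skip the red cut).
#' @param red_threshold_value scalar red threshold.
#' @return Logical matrix, `TRUE` on mitolysosome pixels.
#' @export
build_mask <- function(ratio, peaks, prominence, red = NULL,
                       red_threshold_value = -Inf) {
  ratio <- as.matrix(ratio)
  storage.mode(ratio) <- "double"
  if (nrow(peaks) == 0)
    return(matrix(FALSE, nrow(ratio), ncol(ratio)))
  mask <- flood_tolerance_cpp(ratio, as.integer(peaks$x),
                              as.integer(peaks$y), prominence)
  if (!is.null(red) && is.finite(red_threshold_value))
    mask <- mask & (red >= red_threshold_value)
  mask
}

#' Detect mitolysosomes in a two-channel image
#'
#' Full pipeline: median-smooth both channels, compute the mCherry/GFP ratio
#' image, derive the adaptive red threshold from the smoothed red channel,
#' detect prominence peaks in the ratio image, drop peaks below the red
#' threshold, and grow the mitophagy mask around the survivors.
#'
#' @param image a [two_channel_image()].
#' @param params a [detection_params()].
#' @return An object of class `detection_result`: list with `ratio` (matrix),
#'   `peaks` (data.frame of accepted peaks, 0-based `x`, `y`, `value`),
#'   `mask` (logical matrix), `red_threshold_value`, `red_smooth`, `params`,
#'   and `image_name`.
#' @examples
#' img <- two_channel_image(matrix(10, 16, 16), matrix(10, 16, 16))
#' res <- detect(img)           # red == green: ratio 1 everywhere, no peaks
#' nrow(res$peaks)
#' @export
detect <- function(image, params = detection_params()) {
  stopifnot(inherits(image, "two_channel_image"),
            inherits(params, "detection_params"))
  red_s <- median_smooth(image$red, params$smooth_radius)
  ratio <- compute_ratio(image, params$smooth_radius, params$ratio_thresh)
  thr <- compute_red_threshold(red_s, params$red_stddev_offset)
  peaks <- find_maxima(ratio, params$ratio_thresh)
  peaks <- filter_peaks(peaks, red_s, thr)
  mask <- build_mask(ratio, peaks, params$ratio_thresh, red_s, thr)
  structure(list(ratio = ratio, peaks = peaks, mask = mask,
                 red_threshold_value = thr, red_smooth = red_s,
                 params = params, image_name = image$name),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf(paste0("<detection_result> '%s': %d peak(s), mask %d px, ",
                     "red threshold %.4g\n"),
              x$image_name, nrow(x$peaks), sum(x$mask),
              x$red_threshold_value))
  invisible(x)
}
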
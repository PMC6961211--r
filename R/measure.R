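#' Per-ROI mitophagy measurements
#'
#' Computes the per-region measurement row for one ROI: region area, raw
#' channel intensity statistics, mitolysosome count and density, and mask
#' areas, together with the echoed detection parameters. Intensity means and
#' totals use the raw (unsmoothed) channels — they are reporter-content
#' readouts of the source image — while counts and mask areas come from the
#' detection result.
#'
#' Column semantics (one row of the results table):
#' region area (pixels times `pixel_size_um`^2), green/red means over the
#' ROI, `RGratio = redTotal/greenTotal`, number of accepted peaks inside the
#' rasterized ROI, count per area, count per green mean (a proxy for count
#' per mitochondrial content), mask area inside the ROI, mask area as a
#' percentage of the region, mean mitolysosome size (mask area divided by
#' peak count; 0 when the count is 0), mask area per green mean, and the ROI
#' bounding-box top-left pixel.
#'
#' @param result a [detect()] result.
#' @param image the [two_channel_image()] that produced it.
#' @param roi one ROI ([polygon_roi()] / [mask_roi()]).
#' @param params the [detection_params()] used.
#' @return A one-row data.frame with snake_case measurement columns.
#' @export
measure_roi <- function(result, image, roi, params) {
  stopifnot(inherits(result, "detection_result"),
            inherits(image, "two_channel_image"))
  shape <- dim(image$red)
  rroi <- rasterize_roi(roi, shape)
  npix <- sum(rroi)
  if (npix == 0) stop("ROI '", roi$label, "' rasterizes to 0 pixels")
  ps2 <- image$pixel_size_um^2
  cell_area <- npix * ps2
  green_total <- sum(image$green[rroi])
  red_total <- sum(image$red[rroi])
  green_mean <- green_total / npix
  red_mean <- red_total / npix
  peaks <- result$peaks
  inside <- if (nrow(peaks) > 0)
    rroi[cbind(peaks$y + 1L, peaks$x + 1L)] else logical(0)
  n <- sum(inside)
  ml_area <- sum(result$mask & rroi) * ps2
  idx <- which(rroi, arr.ind = TRUE)
  data.frame(
    image = result$image_name,
    cell_roi = roi$label,
    cell_area_um2 = cell_area,
    green_mean = green_mean,
    red_mean = red_mean,
    green_total = green_total,
    red_total = red_total,
    rg_ratio = red_total / green_total,
    n_mitolysosomes = n,
    nml_per_um2 = n / cell_area,
    nml_over_green = n / green_mean,
    ml_total_area_um2 = ml_area,
    ml_pct_area = 100 * ml_area / cell_area,
    ml_mean_area_um2 = if (n > 0) ml_area / n else 0,
    ml_area_over_green = ml_area / green_mean,
    x_tl = min(idx[, 2]) - 1L,     # 0-based bounding-box top-left
    y_tl = min(idx[, 1]) - 1L,
    ratio_thresh = params$ratio_thresh,
    red_thresh = result$red_threshold_value,
    smooth_rad = params$smooth_radius,
    stringsAsFactors = FALSE)
}

#' Measure every ROI of an image
#'
#' One measurement row per ROI, in set order. Overlapping ROIs are measured
#' independently; a peak falling in an overlap is counted in every ROI that
#' contains it (with a warning).
#'
#' @inheritParams measure_roi
#' @param roi_set a non-empty [roi_set()].
#' @return data.frame with one row per ROI.
#' @export
measure_image <- function(result, image, roi_set, params) {
  stopifnot(inherits(roi_set, "roi_set"))
  if (length(roi_set) == 0) stop("no ROIs found")
  shape <- dim(image$red)
  peaks <- result$peaks
  claimed <- rep(FALSE, nrow(peaks))
  shared <- FALSE
  rows <- lapply(roi_set$rois, function(roi) {
    row <- measure_roi(result, image, roi, params)
    if (nrow(peaks) > 0) {
      rroi <- rasterize_roi(roi, shape)
      inside <- rroi[cbind(peaks$y + 1L, peaks$x + 1L)]
      if (any(inside & claimed)) shared <<- TRUE
      claimed <<- claimed | inside
    }
    row
  })
  if (shared)
    warning("overlapping ROIs: some peaks are counted in more than one ROI")
  do.call(rbind, rows)
}

#' Write the results table as CSV
#'
#' Writes the standard 18-column results header (UTF-8, '.' decimal
#' separator, no quoting): Image, CellROI, CellArea_μm2, greenMean, redMean,
#' RGratio, nMitolysosomes, nML_per_um2, nML_over_green, MLtotalArea_μm2,
#' MLpctArea, MLmeanArea_μm2, MLarea_μm2_over_green, X_tl, Y_tl, ratioThresh,
#' redThresh, smoothRad. An empty input writes a header-only file.
#'
#' @param rows data.frame from [measure_image()] (possibly 0 rows).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(rows, path) {
  internal <- c("image", "cell_roi", "cell_area_um2", "green_mean",
                "red_mean", "rg_ratio", "n_mitolysosomes", "nml_per_um2",
                "nml_over_green", "ml_total_area_um2", "ml_pct_area",
                "ml_mean_area_um2", "ml_area_over_green", "x_tl", "y_tl",
                "ratio_thresh", "red_thresh", "smooth_rad")
  if (is.null(rows) || nrow(rows) == 0) {
    out <- as.data.frame(setNames(rep(list(numeric(0)),
                                      length(internal)), internal))
  } else {
    missing <- setdiff(internal, names(rows))
    if (length(missing))
      stop("results table lacks columns: ", paste(missing, collapse = ", "))
    out <- rows[, internal, drop = FALSE]
  }
  names(out) <- results_columns()
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read back a results CSV
#' @param path CSV written by [write_results_csv()].
#' @return data.frame with the original snake_case column names.
#' @export
read_results_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, encoding = "UTF-8")
  names(df) <- c("image", "cell_roi", "cell_area_um2", "green_mean",
                 "red_mean", "rg_ratio", "n_mitolysosomes", "nml_per_um2",
                 "nml_over_green", "ml_total_area_um2", "ml_pct_area",
                 "ml_mean_area_um2", "ml_area_over_green", "x_tl", "y_tl",
                 "ratio_thresh", "red_thresh", "smooth_rad")
  df
}

#' Write the derived images for one detection
#'
#' Saves, with deterministic names under `out_dir`:
#' `<image>_ratio.tif` (32-bit float ratio image), `<image>_mask.tif`
#' (8-bit, 0/255 mitophagy mask) and `<image>_overlay.png` (red channel in
#' grayscale with ROI outlines in yellow and accepted peaks as cyan crosses).
#'
#' @param result a [detect()] result.
#' @param roi_set the ROIs drawn on the image.
#' @param out_dir output directory (created if needed).
#' @param image optional [two_channel_image()]; its raw red channel is used
#'   as the overlay background (the smoothed one is used when absent).
#' @param pixel_size_um calibration stamped into the TIFF outputs.
#' @return Character vector of the three file paths, invisibly.
#' @export
write_derived_images <- function(result, roi_set, out_dir, image = NULL,
                                 pixel_size_um = 1) {
  stopifnot(inherits(result, "detection_result"))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  base <- file.path(out_dir, result$image_name)
  if (!is.null(image)) pixel_size_um <- image$pixel_size_um
  ratio_path <- paste0(base, "_ratio.tif")
  mask_path <- paste0(base, "_mask.tif")
  overlay_path <- paste0(base, "_overlay.png")
  write_calibrated_tiff(result$ratio, ratio_path,
                        pixel_size_um = pixel_size_um, dtype = "float32")
  write_calibrated_tiff(ifelse(result$mask, 255, 0), mask_path,
                        pixel_size_um = pixel_size_um, dtype = "uint8")

  bg <- if (!is.null(image)) image$red else result$red_smooth
  mx <- max(bg)
  g <- if (mx > 0) bg / mx else bg
  h <- nrow(g); w <- ncol(g)
  rgb <- array(rep(g, 3), dim = c(h, w, 3))
  outline <- matrix(FALSE, h, w)
  for (roi in roi_set$rois) {
    m <- tryCatch(rasterize_roi(roi, c(h, w)),
                  warning = function(w_) matrix(FALSE, h, w))
    if (!any(m)) next
    shifted <- m[c(1, seq_len(h - 1)), ] & m[c(seq_len(h - 1) + 1, h), ] &
      m[, c(1, seq_len(w - 1))] & m[, c(seq_len(w - 1) + 1, w)]
    outline <- outline | (m & !shifted)
  }
  rgb[, , 1][outline] <- 1; rgb[, , 2][outline] <- 1; rgb[, , 3][outline] <- 0
  pk <- result$peaks
  if (nrow(pk) > 0) {
    for (i in seq_len(nrow(pk))) {
      y <- pk$y[i] + 1L; x <- pk$x[i] + 1L
      ys <- pmax(1L, pmin(h, y + (-2:2))); xs <- pmax(1L, pmin(w, x + (-2:2)))
      rgb[, , 1][cbind(ys, x)] <- 0; rgb[, , 2][cbind(ys, x)] <- 1
      rgb[, , 3][cbind(ys, x)] <- 1
      rgb[, , 1][cbind(y, xs)] <- 0; rgb[, , 2][cbind(y, xs)] <- 1
      rgb[, , 3][cbind(y, xs)] <- 1
    }
  }
  png::writePNG(rgb, overlay_path)
  invisible(c(ratio_path, mask_path, overlay_path))
}
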
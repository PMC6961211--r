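# a minimal hand-built detection_result for pure formula checks
fake_result <- function(shape, peaks_xy, mask, name = "fake",
                        red_thresh = 0) {
  structure(list(
    ratio = matrix(1, shape[1], shape[2]),
    peaks = data.frame(x = as.integer(peaks_xy[, 1]),
                       y = as.integer(peaks_xy[, 2]),
                       value = rep(2, nrow(peaks_xy))),
    mask = mask, red_threshold_value = red_thresh,
    red_smooth = matrix(1, shape[1], shape[2]),
    params = detection_params(), image_name = name),
    class = "detection_result")
}

test_that("areas, densities and ratios follow the measurement formulas", {
  # 400-pixel ROI at 0.5 um/px -> 100 um^2
  img <- two_channel_image(matrix(40, 30, 30), matrix(40, 30, 30),
                           pixel_size_um = 0.5, name = "m")
  roi <- polygon_roi(cbind(c(2, 22, 22, 2), c(3, 3, 23, 23)), "cell")
  mask <- matrix(FALSE, 30, 30)
  res <- fake_result(c(30, 30), cbind(integer(0), integer(0)), mask,
                     name = "m")
  row <- measure_roi(res, img, roi, detection_params())
  expect_equal(row$cell_area_um2, 100)
  expect_identical(row$x_tl, 2L)
  expect_identical(row$y_tl, 3L)
  # no peaks: degenerate columns are 0, not NaN
  expect_identical(row$n_mitolysosomes, 0L)
  expect_equal(row$nml_per_um2, 0)
  expect_equal(row$ml_mean_area_um2, 0)
  expect_equal(row$ml_pct_area, 0)

  # greenMean 40, 8 peaks inside -> nML_over_green = 0.2
  pks <- cbind(x = c(5, 8, 11, 14, 5, 8, 11, 14),
               y = c(6, 6, 6, 6, 12, 12, 12, 12))
  mask2 <- matrix(FALSE, 30, 30); mask2[cbind(pks[, 2] + 1, pks[, 1] + 1)] <- TRUE
  res2 <- fake_result(c(30, 30), pks, mask2, name = "m")
  row2 <- measure_roi(res2, img, roi, detection_params())
  expect_equal(row2$green_mean, 40)
  expect_identical(row2$n_mitolysosomes, 8L)
  expect_equal(row2$nml_over_green, 0.2)
  expect_equal(row2$rg_ratio, row2$red_total / row2$green_total)
  expect_equal(row2$ml_mean_area_um2 * 8, row2$ml_total_area_um2)
})

test_that("peaks are attributed to the ROI that contains them", {
  sc <- simple_scene(px = c(10.5, 20.5, 30.5, 48.5, 55.5),
                     py = c(10.5, 20.5, 30.5, 48.5, 55.5),
                     shape = c(64, 64))
  rendered <- render_scene(sc)
  res <- detect(rendered$image)
  expect_identical(nrow(res$peaks), 5L)
  inner <- polygon_roi(cbind(c(4, 40, 40, 4), c(4, 4, 40, 40)), "inner")
  row <- measure_roi(res, rendered$image, inner, detection_params())
  expect_identical(row$n_mitolysosomes, 3L)      # 3 inside, 2 outside
})

test_that("measurements are additive over disjoint ROIs and deterministic", {
  sc <- simple_scene(px = c(12.5, 20.5, 44.5, 52.5),
                     py = c(12.5, 28.5, 40.5, 52.5), shape = c(64, 64))
  rendered <- render_scene(sc)
  img <- rendered$image
  res <- detect(img)
  left <- polygon_roi(cbind(c(3, 32, 32, 3), c(3, 3, 61, 61)), "L")
  right <- polygon_roi(cbind(c(32, 61, 61, 32), c(3, 3, 61, 61)), "R")
  rows <- measure_image(res, img, roi_set(list(left, right)),
                        detection_params())
  expect_identical(nrow(rows), 2L)
  expect_identical(sum(rows$n_mitolysosomes), nrow(res$peaks))
  both <- measure_roi(res, img,
                      polygon_roi(cbind(c(3, 61, 61, 3), c(3, 3, 61, 61)),
                                  "LR"), detection_params())
  expect_equal(sum(rows$ml_total_area_um2), both$ml_total_area_um2)

  # identical duplicate ROIs give identical rows apart from the label
  dup <- suppressWarnings(
    measure_image(res, img,
                  roi_set(list(polygon_roi(left$vertices, "A"),
                               polygon_roi(left$vertices, "B"))),
                  detection_params()))
  expect_warning(
    measure_image(res, img,
                  roi_set(list(polygon_roi(left$vertices, "A"),
                               polygon_roi(left$vertices, "B"))),
                  detection_params()),
    "more than one ROI")
  a <- dup[1, setdiff(names(dup), "cell_roi")]
  b <- dup[2, setdiff(names(dup), "cell_roi")]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("micron-squared quantities scale with the pixel calibration", {
  sc <- simple_scene(px = 20.5, py = 20.5, shape = c(48, 48),
                     pixel_size_um = 0.2)
  rendered <- render_scene(sc)
  res <- detect(rendered$image)
  roi <- rendered$rois$rois[[1]]
  r1 <- measure_roi(res, rendered$image, roi, detection_params())
  doubled <- two_channel_image(rendered$image$red, rendered$image$green,
                               pixel_size_um = 0.4)
  r2 <- measure_roi(res, doubled, roi, detection_params())
  expect_equal(r2$cell_area_um2, 4 * r1$cell_area_um2)
  expect_equal(r2$ml_total_area_um2, 4 * r1$ml_total_area_um2)
  expect_identical(r2$n_mitolysosomes, r1$n_mitolysosomes)
})

test_that("the results CSV carries the exact 18-column header and round-trips", {
  td <- withr::local_tempdir()
  hdr <- c("Image", "CellROI", "CellArea_\u03bcm2", "greenMean", "redMean",
           "RGratio", "nMitolysosomes", "nML_per_um2", "nML_over_green",
           "MLtotalArea_\u03bcm2", "MLpctArea", "MLmeanArea_\u03bcm2",
           "MLarea_\u03bcm2_over_green", "X_tl", "Y_tl",
           "ratioThresh", "redThresh", "smoothRad")

  f0 <- file.path(td, "empty.csv")
  write_results_csv(NULL, f0)
  lines <- readLines(f0, encoding = "UTF-8")
  expect_length(lines, 1)
  expect_identical(strsplit(lines, ",")[[1]], hdr)

  sc <- simple_scene(px = c(12.5, 40.5), py = c(12.5, 40.5),
                     shape = c(56, 56))
  rendered <- render_scene(sc)
  res <- detect(rendered$image)
  rows <- measure_image(res, rendered$image, rendered$rois,
                        detection_params())
  f <- file.path(td, "rows.csv")
  write_results_csv(rows, f)
  expect_length(readLines(f), nrow(rows) + 1L)

  back <- read_results_csv(f)
  for (col in c("cell_area_um2", "green_mean", "red_mean", "rg_ratio",
                "nml_per_um2", "nml_over_green", "ml_total_area_um2",
                "ml_pct_area", "ml_mean_area_um2", "ml_area_over_green",
                "red_thresh")) {
    expect_equal(back[[col]], rows[[col]], tolerance = 1e-6)
  }
  expect_identical(back$n_mitolysosomes, rows$n_mitolysosomes)
})
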
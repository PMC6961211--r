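test_that("median filter matches its definition on closed-form cases", {
  m <- matrix(0, 3, 3); m[2, 2] <- 9
  expect_identical(median_smooth(m, 0), m)          # radius 0 is identity
  expect_equal(median_smooth(m, 1)[2, 2], 0)        # median of {9, 8 zeros}
  expect_identical(median_kernel_size(1), 9L)       # full 3x3 under d^2<=2
  expect_identical(median_kernel_size(2), 21L)      # offsets with d^2<=5
  expect_error(median_smooth(m, -1), "non-negative")
})

test_that("median filter agrees with a per-pixel sort oracle", {
  set.seed(31)
  for (i in 1:6) {
    img <- matrix(sample(0:99, 16 * 16, TRUE), 16, 16)
    for (r in c(1, 2, 3)) {
      expect_equal(median_smooth(img, r), oracle_median_filter(img, r))
    }
  }
})

test_that("ratio image is 1 for matched channels and handles zero green finitely", {
  img <- two_channel_image(matrix(7, 8, 8), matrix(7, 8, 8))
  expect_true(all(compute_ratio(img, 0) == 1))
  img2 <- two_channel_image(matrix(8, 8, 8), matrix(4, 8, 8))
  expect_true(all(compute_ratio(img2, 0) == 2))

  # division-by-zero sentinel: max finite ratio + 2 * ratio_thresh
  red <- matrix(1, 5, 5); green <- matrix(1, 5, 5)
  red[2, 2] <- 1.2                  # background max ratio 1.2
  red[4, 4] <- 5; green[4, 4] <- 0  # red-only pixel
  r <- compute_ratio(two_channel_image(red, green), 0, ratio_thresh = 0.5)
  expect_equal(r[4, 4], 2.2)
  expect_true(all(is.finite(r)))
  # both channels zero -> ratio 0
  red[1, 1] <- 0; green[1, 1] <- 0
  r2 <- compute_ratio(two_channel_image(red, green), 0)
  expect_equal(r2[1, 1], 0)
})

test_that("red threshold is mean + k * population sd over the whole raster", {
  expect_equal(compute_red_threshold(c(0, 0, 10, 10), 0), 5)
  expect_equal(compute_red_threshold(c(0, 0, 10, 10), 1), 10)  # pop sd = 5
  expect_equal(compute_red_threshold(matrix(3, 4, 4), 7), 3)   # sd = 0
  expect_equal(compute_red_threshold(c(0, 0, 10, 10), -1), 0)
})

test_that("find_maxima reproduces canonical prominence cases", {
  expect_identical(nrow(find_maxima(matrix(5, 10, 10), 0.5)), 0L)
  z <- matrix(0, 9, 9); z[5, 5] <- 10
  p <- find_maxima(z, 0.5)
  expect_identical(p$x, 4L); expect_identical(p$y, 4L)
  expect_equal(p$value, 10)

  # two 10s over a 9.8 ridge: merged at tol 0.5, separate at tol 0.1
  r <- matrix(0, 5, 9); r[3, 3] <- 10; r[3, 7] <- 10; r[3, 4:6] <- 9.8
  expect_identical(nrow(find_maxima(r, 0.5)), 1L)
  expect_identical(nrow(find_maxima(r, 0.1)), 2L)

  # border pixels are eligible
  b <- matrix(0, 6, 6); b[1, 1] <- 4
  expect_identical(nrow(find_maxima(b, 1)), 1L)

  # plateau representative: lexicographically smallest (y, x) member
  pl <- matrix(0, 7, 7); pl[3:4, 4:5] <- 6
  pk <- find_maxima(pl, 1)
  expect_identical(c(pk$x, pk$y), c(3L, 2L))

  expect_error(find_maxima(z, 0), "positive")
})

test_that("find_maxima equals the brute-force prominence oracle on seeded rasters", {
  for (s in 1:25) {
    img <- random_raster(s)
    expect_same_peaks(img, sample(c(0.5, 1, 1.5, 2.5, 4), 1))
  }
  for (cs in handmade_maxima_cases()) expect_same_peaks(cs$img, cs$tol)
})

test_that("red-intensity filtering removes dim background peaks only", {
  ratio <- matrix(1, 9, 9); ratio[3, 3] <- 3; ratio[7, 7] <- 3
  red <- matrix(100, 9, 9); red[3, 3] <- 4000; red[7, 7] <- 40
  peaks <- find_maxima(ratio, 0.5)
  expect_identical(nrow(peaks), 2L)
  kept <- filter_peaks(peaks, red, 500)
  expect_identical(nrow(kept), 1L)
  expect_identical(c(kept$x, kept$y), c(2L, 2L))
  expect_identical(nrow(filter_peaks(peaks, red, 1e6)), 0L)  # above image max
  expect_identical(filter_peaks(peaks, red, 0), peaks)       # all pass
})

test_that("mitophagy mask floods maxima within tolerance and applies the red cut", {
  ratio <- matrix(1, 9, 9)
  expect_false(any(build_mask(ratio, data.frame(x = integer(0),
                                                y = integer(0)), 0.5)))
  ratio[5, 5] <- 4
  pk <- find_maxima(ratio, 0.5)
  m <- build_mask(ratio, pk, 0.5)
  expect_identical(which(m), which(ratio == 4))   # isolated pixel only

  # Gaussian-profile punctum: mask = connected pixels with ratio >= peak - tol
  xs <- matrix(rep(1:21, each = 21), 21); ys <- t(xs)
  g <- 1 + 2 * exp(-((xs - 11)^2 + (ys - 11)^2) / (2 * 2^2))
  pk <- find_maxima(g, 0.6)
  m <- build_mask(g, pk, 0.6)
  expect_identical(m, g >= max(g) - 0.6)

  # red cut removes mask pixels below the red threshold
  red <- matrix(0, 21, 21); red[9:13, 9:13] <- 1000
  m2 <- build_mask(g, pk, 0.6, red, 500)
  expect_identical(m2, (g >= max(g) - 0.6) & red >= 500)
})

test_that("detect composes the pipeline and honours its invariants", {
  # matched channels: no peaks, empty mask
  img <- two_channel_image(matrix(1000, 32, 32), matrix(1000, 32, 32))
  res <- detect(img)
  expect_identical(nrow(res$peaks), 0L)
  expect_false(any(res$mask))

  # five well-separated red-only puncta are found exactly
  sc <- simple_scene(px = c(12.5, 40.5, 12.5, 40.5, 26.5),
                     py = c(12.5, 12.5, 40.5, 40.5, 26.5),
                     shape = c(56, 56))
  rendered <- render_scene(sc)
  res <- detect(rendered$image)
  expect_identical(nrow(res$peaks), 5L)
  mm <- match_peaks(res$peaks, rendered$truth)
  expect_identical(unname(mm), c(5L, 0L))

  # invariants: every peak inside the mask, above the red threshold;
  # mask is a subset of {red >= threshold}
  idx <- cbind(res$peaks$y + 1L, res$peaks$x + 1L)
  expect_true(all(res$mask[idx]))
  expect_true(all(res$red_smooth[idx] >= res$red_threshold_value))
  expect_true(all(res$red_smooth[res$mask] >= res$red_threshold_value))

  # every reported peak is a strict-or-plateau local maximum (8-conn)
  for (i in seq_len(nrow(res$peaks))) {
    y <- res$peaks$y[i] + 1L; x <- res$peaks$x[i] + 1L
    nb <- expand.grid(dy = -1:1, dx = -1:1)
    v <- mapply(function(dy, dx) {
      yy <- y + dy; xx <- x + dx
      if (yy < 1 || yy > nrow(res$ratio) || xx < 1 || xx > ncol(res$ratio))
        -Inf else res$ratio[yy, xx]
    }, nb$dy, nb$dx)
    expect_true(all(v <= res$ratio[y, x]))
  }

  # bafilomycin limit: de-quenched puncta disappear
  sc0 <- simple_scene(px = c(12.5, 40.5), py = c(12.5, 40.5),
                      shape = c(56, 56), quench = 0)
  res0 <- detect(render_scene(sc0)$image)
  expect_identical(nrow(res0$peaks), 0L)
})

test_that("counts fall monotonically with prominence and red offset", {
  sc <- make_benchmark_suite(withr::local_tempdir(), n_images = 1, seed = 5,
                             noise_sd = 120, conditions = "induced")
  img <- read_image(file.path(sc$dir, paste0(sc$images[1], ".tif")), 1, 2)
  counts_p <- vapply(c(0.2, 0.4, 0.5, 0.6), function(pt)
    nrow(detect(img, detection_params(ratio_thresh = pt))$peaks), 0L)
  expect_true(all(diff(counts_p) <= 0))
  counts_k <- vapply(c(-2, 0, 1, 2, 3), function(k)
    nrow(detect(img, detection_params(red_stddev_offset = k))$peaks), 0L)
  expect_true(all(diff(counts_k) <= 0))
  # mask area is non-increasing in the red offset (the red cut and the peak
  # set both shrink as k grows; flood regions per surviving peak are fixed)
  areas <- vapply(c(-1, 0, 1, 2), function(k)
    sum(detect(img, detection_params(red_stddev_offset = k))$mask), 0L)
  expect_true(all(diff(areas) <= 0))
})

test_that("detection is invariant to global gain on both channels", {
  sc <- simple_scene(px = c(15.5, 45.5), py = c(20.5, 40.5),
                     shape = c(64, 64), noise_sd = 80, seed = 13)
  rendered <- render_scene(sc)
  base <- detect(rendered$image)
  scaled <- two_channel_image(rendered$image$red * 3.7,
                              rendered$image$green * 3.7,
                              pixel_size_um = rendered$image$pixel_size_um)
  res <- detect(scaled)
  expect_identical(res$peaks[, c("x", "y")], base$peaks[, c("x", "y")])
  expect_identical(res$mask, base$mask)
  expect_equal(res$red_threshold_value, 3.7 * base$red_threshold_value)
})
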
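# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic reporter scene
#'
#' Describes one synthetic two-channel field: cell regions in which red and
#' green reporter signal are spatially correlated (ratio near 1), embedded
#' red-only puncta emulating GFP quenching in mitolysosomes, a background
#' level, and additive Gaussian noise (clipped at 0, then quantized to
#' integer detector units).
#'
#' @param image_shape `(height, width)` in pixels.
#' @param cells list of cells, each `list(polygon = n x 2 vertex matrix,
#'   base_intensity = scalar)`; both channels take `base_intensity` inside
#'   the cell.
#' @param puncta data.frame with columns `x`, `y` (centre, pixel units),
#'   `radius` (pixels), `amplitude` (reporter signal concentrated in the
#'   punctum) and `quench` in `[0, 1]`. Over the punctum footprint the red
#'   channel becomes `base + amplitude` while green becomes
#'   `(base + amplitude) * (1 - quench)`: the punctum carries the same
#'   reporter amount in both fluorophores and lysosomal pH quenches the
#'   green one by `quench`. `quench = 0` emulates bafilomycin-A1
#'   de-quenching (red equals green, the punctum vanishes from the ratio
#'   image). May have 0 rows.
#' @param background_level intensity outside cells.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param seed integer seed; rendering is reproducible for a fixed spec.
#' @param pixel_size_um calibration of the rendered image.
#' @param name image identifier.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_shape, cells, puncta = NULL,
                       background_level = 100, noise_sd = 0, seed = 1,
                       pixel_size_um = 0.16, name = "synthetic") {
  if (is.null(puncta) || NROW(puncta) == 0) {
    puncta <- data.frame(x = numeric(0), y = numeric(0), radius = numeric(0),
                         amplitude = numeric(0), quench = numeric(0))
  }
  puncta <- as.data.frame(puncta)
  stopifnot(all(c("x", "y", "radius", "amplitude", "quench") %in%
                  names(puncta)),
            all(puncta$quench >= 0 & puncta$quench <= 1),
            noise_sd >= 0, background_level >= 0)
  for (i in seq_len(nrow(puncta))) {
    inside <- any(vapply(cells, function(cl)
      point_in_polygon_eo(puncta$x[i], puncta$y[i],
                          cl$polygon[, 1], cl$polygon[, 2]), TRUE))
    if (!inside)
      stop("punctum ", i, " lies outside every cell polygon")
  }
  structure(list(image_shape = as.integer(image_shape), cells = cells,
                 puncta = puncta, background_level = background_level,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 pixel_size_um = pixel_size_um, name = name),
            class = "scene_spec")
}

disk_footprint <- function(cx, cy, radius, h, w) {
  x0 <- max(0L, floor(cx - radius - 1)); x1 <- min(w - 1L, ceiling(cx + radius))
  y0 <- max(0L, floor(cy - radius - 1)); y1 <- min(h - 1L, ceiling(cy + radius))
  if (x0 > x1 || y0 > y1) return(matrix(integer(0), 0, 2))
  xs <- x0:x1; ys <- y0:y1
  px <- rep(xs, each = length(ys)) + 0.5
  py <- rep(ys, times = length(xs)) + 0.5
  keep <- (px - cx)^2 + (py - cy)^2 <= radius^2
  cbind(y = rep(ys, times = length(xs))[keep] + 1L,
        x = rep(xs, each = length(ys))[keep] + 1L)  # 1-based matrix indices
}

#' Render a synthetic scene with ground truth
#'
#' Inside cells both channels equal the cell base intensity, so the ratio is
#' ~1; over each punctum's hard-disk footprint (pixel centres within
#' `radius` of the punctum centre) red becomes `base + amplitude` and green
#' `(base + amplitude) * (1 - quench)`, so the centre ratio is
#' `1 / (1 - quench)` and footprint areas are analytically known. Gaussian
#' noise (sd `noise_sd`) is then added to each channel independently,
#' clipped at 0, and intensities are quantized to integers (detector units).
#'
#' The ground-truth table flags each punctum as detectable when its
#' noiseless centre ratio contrast over the ~1 cell baseline exceeds
#' `prominence` and its noiseless centre red intensity reaches `red_thresh`.
#'
#' @param spec a [scene_spec()].
#' @param prominence peak prominence the caller intends to use.
#' @param red_thresh red threshold the caller intends to use; `NULL` means
#'   the mean of the noiseless rendered red channel (the `k = 0` adaptive
#'   default).
#' @return list with `image` (a [two_channel_image()]), `truth` (data.frame:
#'   `id`, `x`, `y`, `radius_px`, `red_amplitude`, `quench_fraction`,
#'   `footprint_px`, `detectable`) and `rois` (a [roi_set()] of the cell
#'   polygons).
#' @export
render_scene <- function(spec, prominence = 0.5, red_thresh = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  red <- matrix(spec$background_level, h, w)
  green <- matrix(spec$background_level, h, w)
  base_at <- matrix(spec$background_level, h, w)
  rois <- list()
  for (i in seq_along(spec$cells)) {
    cl <- spec$cells[[i]]
    roi <- polygon_roi(cl$polygon, label = sprintf("cell%02d", i))
    rois[[i]] <- roi
    m <- rasterize_roi(roi, c(h, w))
    red[m] <- cl$base_intensity
    green[m] <- cl$base_intensity
    base_at[m] <- cl$base_intensity
  }
  pn <- spec$puncta
  foot_n <- integer(nrow(pn))
  centre_red <- centre_green <- numeric(nrow(pn))
  for (i in seq_len(nrow(pn))) {
    fp <- disk_footprint(pn$x[i], pn$y[i], pn$radius[i], h, w)
    foot_n[i] <- nrow(fp)
    red[fp] <- red[fp] + pn$amplitude[i]
    green[fp] <- (green[fp] + pn$amplitude[i]) * (1 - pn$quench[i])
    ci <- fp[which.min((fp[, 2] - 0.5 - pn$x[i])^2 +
                         (fp[, 1] - 0.5 - pn$y[i])^2), , drop = FALSE]
    centre_red[i] <- red[ci]
    centre_green[i] <- green[ci]
  }
  if (spec$noise_sd > 0) {
    with_seed(spec$seed, {
      red <- red + matrix(rnorm(h * w, 0, spec$noise_sd), h, w)
      green <- green + matrix(rnorm(h * w, 0, spec$noise_sd), h, w)
    })
    red[red < 0] <- 0
    green[green < 0] <- 0
  }
  red <- round(red)
  green <- round(green)
  if (is.null(red_thresh)) {
    # the k = 0 adaptive default, on the noiseless rendering
    noiseless_red <- base_at
    for (i in seq_len(nrow(pn))) {
      fp <- disk_footprint(pn$x[i], pn$y[i], pn$radius[i], h, w)
      noiseless_red[fp] <- noiseless_red[fp] + pn$amplitude[i]
    }
    red_thresh <- mean(noiseless_red)
  }
  ratio_c <- ifelse(centre_green > 0, centre_red / centre_green,
                    ifelse(centre_red > 0, Inf, 0))
  truth <- data.frame(
    id = seq_len(nrow(pn)),
    x = pn$x, y = pn$y,
    radius_px = pn$radius,
    red_amplitude = pn$amplitude,
    quench_fraction = pn$quench,
    footprint_px = foot_n,
    detectable = (ratio_c - 1 > prominence) & (centre_red >= red_thresh))
  if (nrow(pn) == 0) truth$detectable <- logical(0)
  list(image = two_channel_image(red, green,
                                 pixel_size_um = spec$pixel_size_um,
                                 name = spec$name),
       truth = truth,
       rois = roi_set(rois))
}

# octagonal "cell" polygon inscribed in a rectangle (corner cut `c` px)
octagon <- function(x0, y0, x1, y1, c = 8) {
  cbind(c(x0 + c, x1 - c, x1, x1, x1 - c, x0 + c, x0, x0),
        c(y0, y0, y0 + c, y1 - c, y1, y1, y1 - c, y0 + c))
}

# deterministic punctum placement: sample grid sites inside a rectangle with
# spacing >= sep so footprints never interact; centres land on pixel centres
# (integer + 0.5) so disk footprints are symmetric and median-stable
place_puncta <- function(n, x0, y0, x1, y1, sep) {
  gx <- seq(x0, x1, by = sep)
  gy <- seq(y0, y1, by = sep)
  sites <- expand.grid(x = gx, y = gy)
  if (n > nrow(sites))
    stop("cannot place ", n, " puncta with separation ", sep)
  picked <- sites[sample.int(nrow(sites), n), , drop = FALSE]
  picked + matrix(sample(-1:1, 2 * n, replace = TRUE) + 0.5, ncol = 2)
}

#' Generate a batch-compatible synthetic benchmark suite
#'
#' Writes a folder that [run_batch()] can process directly: per image a
#' calibrated two-channel TIFF (channel 1 red, channel 2 green) and an
#' ImageJ ROI zip of the cell outlines, plus one combined ground-truth CSV.
#' Images alternate between an "induced" condition (many puncta, emulating a
#' strong mitophagy stimulus such as iron chelation) and a "control"
#' condition with none, so the suite shows the qualitative induced-vs-control
#' contrast with known truth. Puncta are separated by at least four times
#' their radius and their contrast is far above the default prominence, so
#' with `noise_sd = 0` every punctum is detectable by construction.
#'
#' @param out_dir output folder (created if needed).
#' @param n_images number of images (>= 1).
#' @param seed master seed; all randomness derives from it.
#' @param noise_sd additive noise level (0 for the noiseless suite).
#' @param quench_fraction GFP quench inside puncta; 0 emulates
#'   bafilomycin-A1 treatment (puncta regain green and disappear from the
#'   ratio image).
#' @param conditions condition labels recycled over images; images labelled
#'   `"control"` receive no puncta.
#' @param puncta_range inclusive range of punctum counts for induced images.
#' @param radius_choices punctum radii (pixels) sampled per punctum. The
#'   default 2.5 px gives a 21-pixel digital disk that is invariant under
#'   the radius-1 median kernel, so expected mask areas are exactly the
#'   analytic footprints.
#' @param amplitude red amplitude added inside puncta (DN).
#' @param base_intensity cell reporter intensity (DN).
#' @param background_level background intensity (DN).
#' @param pixel_size_um calibration written into the TIFFs.
#' @return Invisibly, a list with `dir`, `images` (file names), and `truth`
#'   (the combined ground-truth data.frame, also written as `truth.csv`).
#' @export
make_benchmark_suite <- function(out_dir, n_images = 10, seed = 1,
                                 noise_sd = 0, quench_fraction = 0.9,
                                 conditions = c("induced", "control"),
                                 puncta_range = c(5, 50),
                                 radius_choices = 2.5,
                                 amplitude = 2000, base_intensity = 2000,
                                 background_level = 100,
                                 pixel_size_um = 0.16) {
  stopifnot(n_images >= 1)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  h <- w <- 192L
  truth_all <- list()
  images <- character(n_images)
  with_seed(seed, {
    for (i in seq_len(n_images)) {
      cond <- conditions[(i - 1) %% length(conditions) + 1]
      name <- sprintf("img%03d_%s", i, cond)
      cells <- list(
        list(polygon = octagon(8, 8, w / 2 - 6, h - 8),
             base_intensity = base_intensity),
        list(polygon = octagon(w / 2 + 6, 8, w - 8, h - 8),
             base_intensity = base_intensity))
      if (cond == "control") {
        puncta <- NULL
      } else {
        n_pt <- sample(seq(puncta_range[1], puncta_range[2]), 1)
        radii <- radius_choices[sample.int(length(radius_choices), n_pt,
                                           replace = TRUE)]
        sep <- ceiling(4 * max(radius_choices)) + 2
        n1 <- ceiling(n_pt / 2); n2 <- n_pt - n1
        margin <- ceiling(max(radius_choices)) + 10
        p1 <- place_puncta(n1, 8 + margin, 8 + margin,
                           w / 2 - 6 - margin, h - 8 - margin, sep)
        p2 <- if (n2 > 0)
          place_puncta(n2, w / 2 + 6 + margin, 8 + margin,
                       w - 8 - margin, h - 8 - margin, sep)
        else data.frame(x = numeric(0), y = numeric(0))
        puncta <- data.frame(x = c(p1$x, p2$x), y = c(p1$y, p2$y),
                             radius = radii, amplitude = amplitude,
                             quench = quench_fraction)
      }
      sc <- scene_spec(c(h, w), cells, puncta,
                       background_level = background_level,
                       noise_sd = noise_sd,
                       seed = (seed * 1009L + i) %% 2147483647L,
                       pixel_size_um = pixel_size_um, name = name)
      rendered <- render_scene(sc)
      write_two_channel_tiff(rendered$image,
                             file.path(out_dir, paste0(name, ".tif")))
      write_rois(rendered$rois, file.path(out_dir, paste0(name, ".zip")))
      tr <- rendered$truth
      if (nrow(tr) > 0) tr$image <- name
      else tr$image <- character(0)
      truth_all[[i]] <- tr
      images[i] <- name
    }
  })
  truth <- do.call(rbind, truth_all)
  utils::write.table(truth, file.path(out_dir, "truth.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  invisible(list(dir = out_dir, images = images, truth = truth))
}
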
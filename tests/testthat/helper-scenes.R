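# one rectangular cell filling most of the frame, with puncta at the given
# pixel-centre coordinates; mirrors typical widefield acquisition scales
simple_scene <- function(px = numeric(0), py = numeric(0), radius = 2.5,
                         shape = c(64, 64), base = 2000, bg = 100,
                         amplitude = 2000, quench = 0.9, noise_sd = 0,
                         seed = 1, pixel_size_um = 0.16, name = "scene") {
  h <- shape[1]; w <- shape[2]
  cell <- cbind(c(3, w - 3, w - 3, 3), c(3, 3, h - 3, h - 3))
  puncta <- if (length(px))
    data.frame(x = px, y = py, radius = radius, amplitude = amplitude,
               quench = quench)
  else NULL
  scene_spec(shape, list(list(polygon = cell, base_intensity = base)),
             puncta, background_level = bg, noise_sd = noise_sd,
             seed = seed, pixel_size_um = pixel_size_um, name = name)
}

# detected-vs-truth matching: a punctum is recovered if a peak lies within
# `tol_px` of its centre; returns c(n_matched, n_spurious)
match_peaks <- function(peaks, truth, tol_px = 3) {
  if (nrow(truth) == 0) return(c(matched = 0L, spurious = nrow(peaks)))
  if (nrow(peaks) == 0) return(c(matched = 0L, spurious = 0L))
  d2 <- outer(peaks$x + 0.5, truth$x, "-")^2 +
    outer(peaks$y + 0.5, truth$y, "-")^2
  matched <- sum(apply(d2, 2, min) <= tol_px^2)
  spurious <- sum(apply(d2, 1, min) > tol_px^2)
  c(matched = as.integer(matched), spurious = as.integer(spurious))
}
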
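# Shared synthetic fixtures, generated in code at test time.

# single straight horizontal tube with known geometry, noise-free
straight_tube_spec <- function(H = 64, W = 64, row = 32, width = 5,
                               contrast = 0.5, bg = 0.8, seed = 1) {
  phantom_spec(H, W, n_vessels = 1, vessel_width_range = c(width, width),
               vessel_contrast = contrast, background_level = bg,
               illumination_gradient = 0, noise_sigma = 0, seed = seed,
               centerlines = list(cbind(rep(row, W), seq_len(W))))
}

# vertical step edge of a given 0-255 magnitude at column `at`
step_edge_image <- function(H = 40, W = 40, at = 20, lo = 60, hi = 180) {
  m <- matrix(lo, H, W)
  m[, (at + 1):W] <- hi
  m
}

# Stereo pair dominated by a repetitive (periodic) texture with a weak
# aperiodic component and a disparity step: the stripe period (8 px) lies
# inside the search range, so cost minima alias and matching is genuinely
# ambiguous -- the regime in which the two-tier cross rule is compared
# against the single-threshold one.
repetitive_stereo_pair <- function(H = 48, W = 96, period = 8,
                                   d_bg = 3, d_fg = 8, seed = 21) {
  base <- phantom_spec(H, W, n_vessels = 2, noise_sigma = 0.005,
                       seed = seed)
  d <- matrix(d_bg, H, W)
  d[(H %/% 3):(2 * H %/% 3), (W %/% 3):(2 * W %/% 3)] <- d_fg
  st <- make_stereo_pair(stereo_phantom_spec(base, d,
                                             texture_amplitude = 0.01))
  stripes <- matrix(0.12 * sin(2 * pi * col(st$left) / period), H, W)
  # warp the stripes consistently so the periodic texture is genuine scene
  # content rather than independent noise
  left <- pmin(pmax(st$left + stripes, 0), 1)
  right <- st$right
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    tc <- cc - d[r, cc]
    if (tc >= 1 && tc <= W) right[r, tc] <- left[r, cc]
  }
  list(left = left, right = right, disparity = d, valid = st$valid)
}

# tiny labeled set for supervised training tests
labeled_phantoms <- function(n, H = 64, W = 64, seed = 1) {
  lapply(seq_len(n), function(i) {
    ph <- make_vein_phantom(phantom_spec(H, W, n_vessels = 2,
                                         vessel_width_range = c(4, 8),
                                         noise_sigma = 0.02,
                                         seed = seed + 31 * i))
    list(image = ph$image, mask = ph$mask)
  })
}
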
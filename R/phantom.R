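# Synthetic NIR vein phantoms and stereo pairs with ground truth.
#
# NIR light is absorbed by haemoglobin, so veins appear as dark curvilinear
# tubes on a brighter, unevenly illuminated tissue background. The phantom
# generator emulates exactly that: smooth spline centerlines, a Gaussian
# cross-sectional absorption profile, a linear illumination ramp and additive
# Gaussian sensor noise. All intensities live in [0, 1]; quantisation to
# 8 bits happens only at file-writing time.

#' Specification of a synthetic NIR vein phantom
#'
#' @param height,width Image size in pixels.
#' @param n_vessels Number of vessels to draw.
#' @param vessel_width_range Numeric length-2, min/max tube width in pixels
#'   (minimum 1).
#' @param vessel_contrast Fractional intensity drop at the vessel core,
#'   in (0, 1]: core intensity = local background * (1 - contrast).
#' @param background_level Mean background intensity in [0, 1].
#' @param illumination_gradient Fractional left-to-right intensity ramp; the
#'   background runs from `level * (1 - g/2)` to `level * (1 + g/2)`.
#' @param noise_sigma Standard deviation of additive Gaussian noise
#'   (intensity units).
#' @param seed Integer seed; identical specs produce bit-identical phantoms.
#' @param centerlines Optional list of waypoint matrices (row, col), one per
#'   vessel, overriding the random centerlines (used to construct phantoms
#'   with known geometry).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 96, width = 96, n_vessels = 3,
                         vessel_width_range = c(3, 7), vessel_contrast = 0.45,
                         background_level = 0.65, illumination_gradient = 0.2,
                         noise_sigma = 0.02, seed = 1, centerlines = NULL) {
  if (height < 1 || width < 1)
    stop("phantom dimensions must be positive", call. = FALSE)
  if (n_vessels < 0) stop("n_vessels must be >= 0", call. = FALSE)
  if (vessel_width_range[1] < 1)
    stop("minimum vessel width must be >= 1 px", call. = FALSE)
  if (vessel_contrast <= 0 || vessel_contrast > 1)
    stop("vessel_contrast must lie in (0, 1]", call. = FALSE)
  if (background_level < 0 || background_level > 1)
    stop("background_level must lie in [0, 1]", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_vessels = as.integer(n_vessels),
                 vessel_width_range = as.numeric(vessel_width_range),
                 vessel_contrast = vessel_contrast,
                 background_level = background_level,
                 illumination_gradient = illumination_gradient,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 centerlines = centerlines),
            class = "phantom_spec")
}

# Sample one smooth centerline as a cubic spline through jittered waypoints.
# Returns a dense (row, col) polyline. Vessels run roughly across the image,
# half of them transposed so both orientations are exercised.
random_centerline <- function(H, W) {
  transposed <- runif(1) < 0.5
  if (transposed) { tmp <- H; H <- W; W <- tmp }
  nw <- 5
  xs <- seq(1, W, length.out = nw)
  y0 <- runif(1, 0.15 * H, 0.85 * H)
  ys <- y0 + cumsum(c(0, rnorm(nw - 1, 0, 0.08 * H)))
  ys <- pmin(pmax(ys, 2), H - 1)
  s <- spline(xs, ys, n = 4L * W)
  pts <- cbind(row = s$y, col = s$x)
  if (transposed) pts <- pts[, 2:1]
  colnames(pts) <- c("row", "col")
  pts
}

rasterize_points <- function(pts, H, W) {
  ij <- cbind(pmin(pmax(round(pts[, 1]), 1), H),
              pmin(pmax(round(pts[, 2]), 1), W))
  unique(ij)
}

# Distance (in pixels) from every pixel to the rasterised polyline.
dist_to_curve <- function(pts_ij, H, W) {
  m <- matrix(0L, H, W)
  m[pts_ij] <- 1L
  # distance to the nearest curve pixel = EDT of the complement
  as.matrix(EBImage::distmap(1 - m, metric = "euclidean"))
}

#' Generate a synthetic NIR vein phantom
#'
#' Draws `n_vessels` smooth dark tubes over a ramped noisy background and
#' returns the image together with its ground truth.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `image` (matrix in \[0,1\]), `mask` (binary
#'   matrix marking tube pixels, tube radius = width/2 around the
#'   centerline), `centerlines` (list of (row, col) coordinate matrices of
#'   the rasterised generating curves) and `centerline_mask`.
#' @export
make_vein_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$height; W <- spec$width
  with_seed(spec$seed, {
    ramp <- spec$background_level *
      (1 + spec$illumination_gradient * (seq(0, 1, length.out = W) - 0.5))
    bg <- matrix(rep(clamp01(ramp), each = H), H, W)
    factor <- matrix(1, H, W)
    mask <- matrix(0L, H, W)
    cmask <- matrix(0L, H, W)
    centerlines <- list()
    if (spec$n_vessels > 0) {
      for (v in seq_len(spec$n_vessels)) {
        pts <- if (!is.null(spec$centerlines)) spec$centerlines[[v]]
               else random_centerline(H, W)
        w <- runif(1, spec$vessel_width_range[1], spec$vessel_width_range[2])
        ij <- rasterize_points(pts, H, W)
        D <- dist_to_curve(ij, H, W)
        prof <- exp(-D^2 / (2 * (w / 4)^2))
        factor <- pmin(factor, 1 - spec$vessel_contrast * prof)
        mask[D <= w / 2] <- 1L
        cmask[ij] <- 1L
        centerlines[[v]] <- ij
      }
    }
    img <- bg * factor
    if (spec$noise_sigma > 0)
      img <- img + matrix(rnorm(H * W, 0, spec$noise_sigma), H, W)
    list(image = clamp01(img), mask = mask, centerlines = centerlines,
         centerline_mask = cmask)
  })
}

#' Specification of a synthetic stereo pair
#'
#' @param base A [phantom_spec()] describing the left image content.
#' @param disparity Either a single nonnegative number or an H x W matrix of
#'   nonnegative disparities (pixels). Values are rounded to integers for
#'   warping; the returned ground truth stores the rounded field.
#' @param texture_amplitude Standard deviation of the smooth random texture
#'   added to the left image so that homogeneous regions stay matchable.
#' @return An object of class `stereo_phantom_spec`.
#' @export
stereo_phantom_spec <- function(base, disparity = 6, texture_amplitude = 0.1) {
  stopifnot(inherits(base, "phantom_spec"))
  d <- if (is.matrix(disparity)) disparity
       else matrix(disparity, base$height, base$width)
  if (any(d < 0)) stop("disparity must be nonnegative", call. = FALSE)
  if (max(d) >= base$width)
    stop("disparity must be smaller than the image width", call. = FALSE)
  structure(list(base = base, disparity = round(d),
                 texture_amplitude = texture_amplitude),
            class = "stereo_phantom_spec")
}

#' Generate a rectified synthetic stereo pair with ground-truth disparity
#'
#' The right image is the forward warp of the left by the disparity field
#' (`left(r, c)` maps to `right(r, c - d(r, c))`). Occlusions are resolved by
#' visibility: when several left pixels land on the same right column the
#' rightmost one wins, and the losers are marked invalid in the ground-truth
#' validity mask. Disoccluded right-image holes are filled from the nearest
#' warped neighbour along the row.
#'
#' @param spec A [stereo_phantom_spec()].
#' @return List with `left`, `right` (matrices in \[0,1\]), `disparity`
#'   (ground-truth integer field), `valid` (binary visibility mask for the
#'   left image) and `phantom` (the underlying phantom ground truth).
#' @export
make_stereo_pair <- function(spec) {
  stopifnot(inherits(spec, "stereo_phantom_spec"))
  ph <- make_vein_phantom(spec$base)
  H <- spec$base$height; W <- spec$base$width
  left <- ph$image
  if (spec$texture_amplitude > 0) {
    tex <- with_seed(spec$base$seed + 7919L, {
      t0 <- gaussian_blur(matrix(rnorm(H * W), H, W), 1.2)
      t0 / stats::sd(t0) * spec$texture_amplitude
    })
    left <- clamp01(left + tex)
  }
  d <- spec$disparity
  right <- matrix(NA_real_, H, W)
  winner <- matrix(NA_integer_, H, W)
  for (r in seq_len(H)) {
    for (cc in seq_len(W)) {
      tc <- cc - d[r, cc]
      if (tc >= 1 && tc <= W) {
        right[r, tc] <- left[r, cc]
        winner[r, tc] <- cc
      }
    }
  }
  valid <- matrix(0L, H, W)
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    tc <- cc - d[r, cc]
    if (tc >= 1 && tc <= W && identical(winner[r, tc], cc))
      valid[r, cc] <- 1L
  }
  # fill disoccluded holes from the nearest filled pixel along the row
  for (r in seq_len(H)) {
    row <- right[r, ]
    if (anyNA(row)) {
      filled <- which(!is.na(row))
      if (length(filled) == 0) row[] <- mean(left[r, ]) else {
        for (cc in which(is.na(row))) {
          nb <- filled[which.min(abs(filled - cc))]
          row[cc] <- row[nb]
        }
      }
      right[r, ] <- row
    }
  }
  list(left = left, right = right, disparity = d, valid = valid, phantom = ph)
}

#' Generate a set of unlabeled phantom images
#'
#' Stands in for an unlabeled NIR image collection used for self-supervised
#' pretraining. Each image uses a seed derived from `seed` so the whole set
#' is reproducible.
#'
#' @param n Number of images (>= 1).
#' @param spec A [phantom_spec()] used as template.
#' @param seed Integer master seed.
#' @return List of `n` image matrices (no masks).
#' @export
make_unlabeled_set <- function(n, spec, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  lapply(seq_len(n), function(i) {
    si <- spec
    si$seed <- as.integer((seed + 104729 * i) %% .Machine$integer.max)
    make_vein_phantom(si)$image
  })
}
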
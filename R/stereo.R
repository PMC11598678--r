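# Variable-weight AD-Census stereo matching with cross-based cost
# aggregation (CBCA).
#
# The matching cost between left pixel p and right candidate q = p - d is a
# convex combination of a normalised absolute-difference (AD) term and a
# normalised census-Hamming term,
#
#   C(p, q) = alpha rho(C_AD, lambda_AD) + (1 - alpha) rho(C_C, lambda_C),
#   rho(c, lambda) = 1 - exp(-c / lambda).
#
# In the variable-weight scheme alpha = 1 - exp(-1 / h_min), where h_min is
# the minimum cross-arm extension of p: near intensity edges the arms are
# short, h_min is small, alpha is large and the AD term dominates; inside
# homogeneous regions the census term dominates. Costs are aggregated over
# adaptive cross-shaped support regions, either with the classic
# single-threshold arm rule (mode "original") or the two-tier rule
# (mode "optimized") that uses a tight threshold far from the pixel and
# additionally bounds consecutive-pixel differences, preventing arms from
# leaking across edges while keeping long arms in weak texture.

#' Stereo matching parameters
#'
#' @param d_min,d_max Disparity search range in pixels (`d_max > d_min >= 0`).
#' @param census_window Odd (height, width) of the census window.
#' @param lambda_ad,lambda_c Cost normalisation controls for the AD and
#'   census terms (intensities on the 0-255 scale).
#' @param L,tau Arm length cap and grey threshold of the single-threshold
#'   cross rule (mode "original").
#' @param L1,L2,tau1,tau2 Two-tier arm/threshold parameters (mode
#'   "optimized"); requires `L1 > L2 >= 1` and `tau1 > tau2 > 0`.
#' @param iterations Number of aggregation passes; pass order alternates
#'   starting horizontal-first.
#' @param lr_threshold Left-right consistency tolerance in pixels.
#' @param mode Cross construction rule: "original" or "optimized".
#' @param weight_mode "variable" (alpha from h_min) or "fixed" (alpha 0.5,
#'   the classic equal-weight AD-Census; `alpha_fixed` overrides).
#' @param alpha_fixed Fixed weight used when `weight_mode = "fixed"`.
#' @return Object of class `stereo_params`.
#' @export
stereo_params <- function(d_min = 0, d_max = 16, census_window = c(9, 7),
                          lambda_ad = 10, lambda_c = 30,
                          L = 17, tau = 20,
                          L1 = 34, L2 = 17, tau1 = 20, tau2 = 6,
                          iterations = 2, lr_threshold = 1,
                          mode = c("optimized", "original"),
                          weight_mode = c("variable", "fixed"),
                          alpha_fixed = 0.5) {
  mode <- match.arg(mode)
  weight_mode <- match.arg(weight_mode)
  if (d_max <= d_min || d_min < 0)
    stop("need d_max > d_min >= 0", call. = FALSE)
  assert_odd(census_window[1], "census window height")
  assert_odd(census_window[2], "census window width")
  if (mode == "optimized" && (L1 <= L2 || L2 < 1 || tau1 <= tau2 || tau2 <= 0))
    stop("optimized mode requires L1 > L2 >= 1 and tau1 > tau2 > 0",
         call. = FALSE)
  structure(list(d_min = as.integer(d_min), d_max = as.integer(d_max),
                 census_window = as.integer(census_window),
                 lambda_ad = lambda_ad, lambda_c = lambda_c,
                 L = as.integer(L), tau = tau,
                 L1 = as.integer(L1), L2 = as.integer(L2),
                 tau1 = tau1, tau2 = tau2,
                 iterations = as.integer(iterations),
                 lr_threshold = lr_threshold, mode = mode,
                 weight_mode = weight_mode, alpha_fixed = alpha_fixed),
            class = "stereo_params")
}

#' Census transform of an image
#'
#' Per-pixel bit vector over the window neighbours (rows top to bottom,
#' columns left to right within a row, centre skipped): bit = 1 iff the
#' neighbour is darker than the centre. Borders use reflected neighbours.
#' The census matching cost between two pixels is the Hamming distance of
#' their bit vectors.
#'
#' @param img Grayscale matrix (\[0,1\] or 0-255).
#' @param window Odd (height, width).
#' @return Integer 0/1 array of dim (H, W, h*w - 1).
#' @export
census_transform <- function(img, window = c(9, 7)) {
  assert_gray(img)
  assert_odd(window[1], "window height")
  assert_odd(window[2], "window width")
  cpp_census(to_scale255(img), window[1], window[2])
}

#' Absolute-difference matching cost for a single pixel/disparity
#'
#' `|I_L(r, c) - I_R(r, c - d)|` on the 0-255 intensity scale; `Inf` when
#' the matched pixel falls outside the frame (the normalised cost of `Inf`
#' is the maximum, 1).
#'
#' @param left,right Grayscale matrices.
#' @param p Length-2 (row, col) position in the left image.
#' @param d Disparity in pixels.
#' @export
ad_cost <- function(left, right, p, d) {
  L <- to_scale255(left); R <- to_scale255(right)
  q <- p[2] - d
  if (q < 1 || q > ncol(R)) return(Inf)
  abs(L[p[1], p[2]] - R[p[1], q])
}

#' Exponential cost normalisation
#'
#' `rho(c, lambda) = 1 - exp(-c / lambda)`: zero at zero cost, strictly
#' increasing, approaching 1 for large costs.
#'
#' @param c Nonnegative cost (vectorised).
#' @param lambda Positive control parameter.
#' @export
rho <- function(c, lambda) {
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  1 - exp(-c / lambda)
}

#' Adaptive cross arms of an image
#'
#' For each pixel, the maximal extension in the four directions under the
#' active rule; traversal stops at the first failing candidate. See
#' [stereo_params()] for the two rules.
#'
#' @param img Grayscale matrix.
#' @param params A [stereo_params()].
#' @return Object of class `cross_arms`: list of integer matrices `left`,
#'   `right`, `up`, `down` (extensions, >= 0).
#' @export
build_cross <- function(img, params = stereo_params()) {
  arms <- cpp_build_cross(to_scale255(img), params$mode == "optimized",
                          params$L, params$tau, params$L1, params$L2,
                          params$tau1, params$tau2)
  structure(arms, class = "cross_arms")
}

#' Minimum arm length map
#'
#' Per-pixel minimum of the four arm extensions, clamped to >= 1.
#' @param arms A [build_cross()] result.
#' @export
hmin_map <- function(arms) {
  pmax(pmin(arms$left, arms$right, arms$up, arms$down), 1)
}

#' Variable AD/census weight from the minimum arm length
#'
#' `alpha = 1 - exp(-1 / h_min)`, strictly decreasing in `h_min`: large at
#' edges (short arms), small in homogeneous interiors.
#'
#' @param h_min Minimum arm length (vectorised; clamped to >= 1).
#' @export
alpha_weight <- function(h_min) {
  1 - exp(-1 / pmax(h_min, 1))
}

#' Combined AD-Census cost volume
#'
#' @param left,right Rectified grayscale pair.
#' @param params A [stereo_params()].
#' @param arms_left Optional precomputed [build_cross()] of the left image
#'   (used for the variable weight).
#' @return Numeric array of dim (H, W, d_max - d_min + 1); values in
#'   \[0, 1) except the out-of-frame sentinel 1.
#' @export
combined_cost_volume <- function(left, right, params = stereo_params(),
                                 arms_left = NULL) {
  if (!identical(dim(left), dim(right)))
    stop("left and right images must have the same shape", call. = FALSE)
  alpha <- if (params$weight_mode == "variable") {
    if (is.null(arms_left)) arms_left <- build_cross(left, params)
    alpha_weight(hmin_map(arms_left))
  } else {
    matrix(params$alpha_fixed, nrow(left), ncol(left))
  }
  if (any(alpha < 0 | alpha > 1)) stop("alpha out of range", call. = FALSE)
  v <- cpp_cost_volume(to_scale255(left), to_scale255(right),
                       params$census_window[1], params$census_window[2],
                       alpha, params$lambda_ad, params$lambda_c,
                       params$d_min, params$d_max)
  attr(v, "d_min") <- params$d_min
  v
}

#' Cross-based cost aggregation
#'
#' Each pass averages costs over the adaptive support region: the union,
#' over the pixel's vertical arm, of those pixels' horizontal arms
#' (horizontal-first), or the transpose. The support combines the left
#' pixel's cross with the matched right pixel's cross (per-direction
#' minimum). `iterations` passes are applied with alternating order.
#'
#' @param volume Cost volume from [combined_cost_volume()].
#' @param arms_left,arms_right [build_cross()] of the two images.
#' @param params A [stereo_params()].
#' @param iterations Number of passes (default from `params`).
#' @param horizontal_first Orientation of the first pass.
#' @return Aggregated cost volume.
#' @export
aggregate_cbca <- function(volume, arms_left, arms_right,
                           params = stereo_params(),
                           iterations = params$iterations,
                           horizontal_first = TRUE) {
  d_min <- attr(volume, "d_min")
  if (is.null(d_min)) d_min <- params$d_min
  v <- volume
  hf <- horizontal_first
  for (i in seq_len(iterations)) {
    v <- cpp_cbca_pass(v, unclass(arms_left), unclass(arms_right), d_min, hf)
    hf <- !hf
  }
  attr(v, "d_min") <- d_min
  v
}

#' Winner-takes-all disparity from a cost volume
#'
#' Per-pixel argmin over disparity; ties break toward the smaller
#' disparity.
#'
#' @param volume Cost volume with `d_min` attribute.
#' @param d_min Disparity of the first plane (default from the attribute).
#' @return Disparity matrix in pixels.
#' @export
wta_disparity <- function(volume, d_min = attr(volume, "d_min")) {
  if (is.null(d_min)) d_min <- 0L
  dm <- dim(volume)
  m <- matrix(volume, dm[1] * dm[2], dm[3])
  idx <- max.col(-m, ties.method = "first")
  matrix(d_min + idx - 1L, dm[1], dm[2])
}

#' Left-right consistency refinement
#'
#' Pixels whose left and right disparities disagree by more than
#' `lr_threshold` are invalidated, then filled with the smaller of the
#' nearest valid disparities along the row (background-favouring fill for
#' occlusions), and finally smoothed with a validity-aware 3x3 median.
#' Unfillable pixels stay `NA`.
#'
#' @param d_left,d_right Disparity maps of the two views (left-referenced
#'   and right-referenced).
#' @param params A [stereo_params()] (uses `lr_threshold`).
#' @return Refined left disparity with `NA` marking invalid pixels.
#' @export
lr_refine <- function(d_left, d_right, params = stereo_params()) {
  H <- nrow(d_left); W <- ncol(d_left)
  d <- matrix(NA_real_, H, W)
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    dl <- d_left[r, cc]
    q <- cc - dl
    if (q >= 1 && q <= W && is.finite(d_right[r, q]) &&
        abs(dl - d_right[r, q]) <= params$lr_threshold)
      d[r, cc] <- dl
  }
  if (!any(is.finite(d))) {
    warning("left-right check invalidated every pixel")
    return(d)
  }
  filled <- d
  for (r in seq_len(H)) {
    row <- d[r, ]
    ok <- which(is.finite(row))
    if (length(ok) == 0) next
    for (cc in which(!is.finite(row))) {
      lv <- ok[ok < cc]; rv <- ok[ok > cc]
      cand <- c(if (length(lv)) row[max(lv)], if (length(rv)) row[min(rv)])
      filled[r, cc] <- min(cand)
    }
  }
  out <- filled
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    i0 <- max(1, r - 1):min(H, r + 1)
    j0 <- max(1, cc - 1):min(W, cc + 1)
    v <- filled[i0, j0]
    v <- v[is.finite(v)]
    if (length(v)) out[r, cc] <- median(v)
  }
  out
}

#' Full stereo matching pipeline
#'
#' Builds crosses for both images, computes the combined cost volume,
#' aggregates it, takes the WTA disparity of both views (the right view via
#' `C_R(r, c, d) = C_L(r, c + d, d)`) and applies left-right refinement.
#'
#' @param left,right Rectified grayscale pair.
#' @param params A [stereo_params()].
#' @param refine Apply [lr_refine()] (default TRUE).
#' @return List with `disparity` (refined, `NA` = invalid), `d_left`,
#'   `d_right`, `volume` (aggregated).
#' @export
match_stereo <- function(left, right, params = stereo_params(),
                         refine = TRUE) {
  arms_l <- build_cross(left, params)
  arms_r <- build_cross(right, params)
  vol <- combined_cost_volume(left, right, params, arms_left = arms_l)
  vol <- aggregate_cbca(vol, arms_l, arms_r, params)
  d_left <- wta_disparity(vol)
  H <- nrow(left); W <- ncol(left); D <- dim(vol)[3]
  vr <- array(1, dim(vol))          # out-of-frame sentinel cost
  for (t in seq_len(D)) {
    dd <- params$d_min + t - 1L
    if (dd < W) {
      src <- seq_len(W - dd)
      vr[, src, t] <- vol[, src + dd, t]
    }
  }
  attr(vr, "d_min") <- params$d_min
  d_right <- wta_disparity(vr)
  disparity <- if (refine) lr_refine(d_left, d_right, params) else d_left
  list(disparity = disparity, d_left = d_left, d_right = d_right,
       volume = vol)
}
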
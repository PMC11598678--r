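# Preprocessing: contrast-limited adaptive histogram equalisation followed
# by median filtering. CLAHE lifts the dark vascular regions that NIR
# absorption produces; the median filter removes impulse-like sensor noise
# while preserving vessel edges better than mean filtering.

#' Preprocessing configuration
#'
#' @param tile_grid Integer length-2 (rows, cols) of CLAHE tiles.
#' @param clip_limit Relative histogram clip factor (> 0); 1 disables
#'   equalisation beyond the identity, larger values allow more contrast.
#' @param median_kernel Odd integer median window size (1 disables).
#' @return Object of class `preprocess_config`.
#' @export
preprocess_config <- function(tile_grid = c(8, 8), clip_limit = 2,
                              median_kernel = 5) {
  if (clip_limit <= 0) stop("clip_limit must be > 0", call. = FALSE)
  assert_odd(median_kernel, "median_kernel")
  structure(list(tile_grid = as.integer(tile_grid), clip_limit = clip_limit,
                 median_kernel = as.integer(median_kernel)),
            class = "preprocess_config")
}

#' Contrast-limited adaptive histogram equalisation
#'
#' Tile histograms are clipped at the limit with the excess redistributed,
#' and the per-tile mappings are bilinearly interpolated between neighbouring
#' tiles (Zuiderveld's algorithm, via EBImage). The mapping is monotone
#' non-decreasing per tile; on a constant image the output is constant (the
#' clipped-histogram redistribution may shift the value by a few grey
#' levels).
#'
#' @param img Single-channel matrix in \[0,1\].
#' @param cfg A [preprocess_config()].
#' @return Enhanced image, same shape, values in \[0,1\].
#' @export
clahe <- function(img, cfg = preprocess_config()) {
  assert_gray(img)
  out <- EBImage::clahe(t(img), nx = cfg$tile_grid[2], ny = cfg$tile_grid[1],
                        limit = cfg$clip_limit)
  t(as.matrix(out))
}

#' Median filtering with reflected borders
#'
#' @param img Single-channel numeric matrix.
#' @param kernel Odd window size in pixels.
#' @return Filtered image of the same shape.
#' @export
median_filter <- function(img, kernel = 5) {
  assert_gray(img)
  assert_odd(kernel, "kernel")
  if (kernel == 1) return(img)
  cpp_median_filter(img, as.integer(kernel))
}

#' Full preprocessing pipeline: CLAHE then median filtering
#'
#' @inheritParams clahe
#' @return Preprocessed image with the resolved configuration attached as
#'   attribute `config`.
#' @export
preprocess_pipeline <- function(img, cfg = preprocess_config()) {
  out <- median_filter(clahe(img, cfg), cfg$median_kernel)
  attr(out, "config") <- cfg
  out
}

#' Plain histogram equalisation (comparison baseline)
#'
#' Global histogram equalisation over 256 bins; provided only as a baseline
#' against which CLAHE is compared in the test-suite, not as a pipeline step.
#' @param img Single-channel matrix in \[0,1\].
#' @keywords internal
hist_equalize <- function(img) {
  assert_gray(img)
  v <- as.integer(round(clamp01(img) * 255))
  h <- tabulate(v + 1L, 256L)
  cdf <- cumsum(h)
  cdfmin <- cdf[which(cdf > 0)[1]]
  lut <- (cdf - cdfmin) / max(1, length(v) - cdfmin)
  matrix(lut[v + 1L], nrow(img), ncol(img))
}
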
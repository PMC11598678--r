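# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Accept [0,1] float or 0-255 images; return the 0-255 scale used by the
# stereo cost functions and census thresholds.
to_scale255 <- function(img) {
  stopifnot(is.matrix(img))
  if (max(img) <= 1 + 1e-12) img * 255 else img
}

assert_gray <- function(img, name = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(name, " must be a single-channel numeric matrix", call. = FALSE)
  invisible(img)
}

assert_odd <- function(k, name = "kernel") {
  if (length(k) != 1 || k < 1 || k %% 2 != 1)
    stop(name, " must be a positive odd integer", call. = FALSE)
  invisible(k)
}

is_binary <- function(x) all(x %in% c(0, 1, FALSE, TRUE))

# 8-connected component labelling of a binary matrix (skeleton-sized inputs).
label8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  idx <- which(mask > 0)
  nextlab <- 0L
  for (s in idx) {
    if (lab[s] != 0L) next
    nextlab <- nextlab + 1L
    queue <- s
    lab[s] <- nextlab
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      i <- (p - 1L) %% H + 1L; j <- (p - 1L) %/% H + 1L
      for (dj in -1:1) for (di in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > H || jj < 1 || jj > W) next
        q <- (jj - 1L) * H + ii
        if (mask[q] > 0 && lab[q] == 0L) {
          lab[q] <- nextlab
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# Integer pixel coordinates (row, col) on the segment between two pixels.
bresenham <- function(p0, p1) {
  x0 <- p0[2]; y0 <- p0[1]; x1 <- p1[2]; y1 <- p1[1]
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx - dy
  pts <- matrix(0L, dx + dy + 1L, 2)
  n <- 0L
  repeat {
    n <- n + 1L
    pts[n, ] <- c(y0, x0)
    if (x0 == x1 && y0 == y1) break
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x0 <- x0 + sx }
    if (e2 < dx) { err <- err + dx; y0 <- y0 + sy }
  }
  pts[seq_len(n), , drop = FALSE]
}

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Gaussian smoothing with reflected borders.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel1d(sigma)
  cpp_sepconv_reflect(img, k, k)
}
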
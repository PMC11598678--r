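# Independent brute-force reference implementations used to validate the
# compiled stereo kernels on small instances. These share no code with the
# package internals: plain nested loops, explicit region enumeration.

reflect_idx <- function(i, n) {
  # symmetric (edge-inclusive) reflection, 1-based
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

oracle_census_bits <- function(img, i, j, wh, ww) {
  H <- nrow(img); W <- ncol(img)
  rh <- (wh - 1) / 2; rw <- (ww - 1) / 2
  bits <- integer(0)
  ctr <- img[i, j]
  for (di in -rh:rh) for (dj in -rw:rw) {
    if (di == 0 && dj == 0) next
    v <- img[reflect_idx(i + di, H), reflect_idx(j + dj, W)]
    bits <- c(bits, as.integer(v < ctr))
  }
  bits
}

oracle_census_cost <- function(left, right, i, jl, jr, wh, ww) {
  sum(oracle_census_bits(left, i, jl, wh, ww) !=
        oracle_census_bits(right, i, jr, wh, ww))
}

oracle_arm <- function(img, i, j, di, dj, params) {
  H <- nrow(img); W <- ncol(img)
  ctr <- img[i, j]
  optimized <- params$mode == "optimized"
  emax <- if (optimized) params$L1 else params$L - 1
  ext <- 0L
  for (e in seq_len(max(emax, 0))) {
    ii <- i + e * di; jj <- j + e * dj
    if (ii < 1 || ii > H || jj < 1 || jj > W) break
    if (optimized) {
      th <- if (e <= params$L2) params$tau1 else params$tau2
      ok <- abs(ctr - img[ii, jj]) < th
      i2 <- ii + di; j2 <- jj + dj
      if (ok && i2 >= 1 && i2 <= H && j2 >= 1 && j2 <= W)
        ok <- abs(img[ii, jj] - img[i2, j2]) < th
    } else {
      ok <- abs(ctr - img[ii, jj]) < params$tau
    }
    if (!ok) break
    ext <- e
  }
  ext
}

oracle_cross <- function(img, params) {
  H <- nrow(img); W <- ncol(img)
  arms <- list(left = matrix(0L, H, W), right = matrix(0L, H, W),
               up = matrix(0L, H, W), down = matrix(0L, H, W))
  dirs <- list(left = c(0, -1), right = c(0, 1), up = c(-1, 0),
               down = c(1, 0))
  for (nm in names(dirs))
    for (j in seq_len(W)) for (i in seq_len(H))
      arms[[nm]][i, j] <- oracle_arm(img, i, j, dirs[[nm]][1],
                                     dirs[[nm]][2], params)
  arms
}

oracle_cost_volume <- function(left, right, params, alpha) {
  H <- nrow(left); W <- ncol(left)
  D <- params$d_max - params$d_min + 1
  wh <- params$census_window[1]; ww <- params$census_window[2]
  v <- array(NA_real_, c(H, W, D))
  for (t in seq_len(D)) {
    d <- params$d_min + t - 1
    for (j in seq_len(W)) for (i in seq_len(H)) {
      q <- j - d
      if (q < 1 || q > W) { v[i, j, t] <- 1; next }
      cad <- abs(left[i, j] - right[i, q])
      cc <- oracle_census_cost(left, right, i, j, q, wh, ww)
      a <- alpha[i, j]
      v[i, j, t] <- a * (1 - exp(-cad / params$lambda_ad)) +
        (1 - a) * (1 - exp(-cc / params$lambda_c))
    }
  }
  v
}

# one CBCA pass by explicit support-region enumeration
oracle_cbca_pass <- function(vol, armsL, armsR, d_min, horizontal_first) {
  dm <- dim(vol); H <- dm[1]; W <- dm[2]; D <- dm[3]
  eff <- function(i, j, d) {
    q <- j - d
    if (q >= 1 && q <= W)
      c(left = min(armsL$left[i, j], armsR$left[i, q]),
        right = min(armsL$right[i, j], armsR$right[i, q]),
        up = min(armsL$up[i, j], armsR$up[i, q]),
        down = min(armsL$down[i, j], armsR$down[i, q]))
    else
      c(left = armsL$left[i, j], right = armsL$right[i, j],
        up = armsL$up[i, j], down = armsL$down[i, j])
  }
  out <- array(NA_real_, dm)
  for (t in seq_len(D)) {
    d <- d_min + t - 1
    for (j in seq_len(W)) for (i in seq_len(H)) {
      e0 <- eff(i, j, d)
      vals <- c()
      if (horizontal_first) {
        for (dt in (-e0["up"]):(e0["down"])) {
          ii <- i + dt
          e1 <- eff(ii, j, d)
          vals <- c(vals, vol[ii, (j - e1["left"]):(j + e1["right"]), t])
        }
      } else {
        for (ds in (-e0["left"]):(e0["right"])) {
          jj <- j + ds
          e1 <- eff(i, jj, d)
          vals <- c(vals, vol[(i - e1["up"]):(i + e1["down"]), jj, t])
        }
      }
      out[i, j, t] <- mean(vals)
    }
  }
  out
}

# brute-force visibility for the stereo phantom: a left pixel is visible
# iff no other left pixel in the same row with a larger column lands on
# the same right-image column
oracle_visibility <- function(d) {
  H <- nrow(d); W <- ncol(d)
  vis <- matrix(0L, H, W)
  for (r in seq_len(H)) {
    target <- seq_len(W) - d[r, ]
    for (cc in seq_len(W)) {
      tc <- target[cc]
      if (tc < 1 || tc > W) next
      later <- which(target == tc)
      if (max(later) == cc) vis[r, cc] <- 1L
    }
  }
  vis
}
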
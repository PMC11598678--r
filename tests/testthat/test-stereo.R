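test_that("census transform matches the documented bit order", {
  img <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9) / 255, 3, 3, byrow = TRUE)
  ct <- census_transform(img, c(3, 3))
  expect_equal(as.integer(ct[2, 2, ]), c(1, 1, 1, 1, 0, 0, 0, 0))

  const <- matrix(0.4, 8, 8)
  expect_true(all(census_transform(const, c(3, 3)) == 0))
  expect_error(census_transform(const, c(4, 3)), "odd")
})

test_that("census cost volume equals the brute-force oracle", {
  set.seed(13)
  left <- matrix(runif(12 * 12, 0, 255), 12, 12)
  right <- matrix(runif(12 * 12, 0, 255), 12, 12)
  for (wm in c("fixed", "variable")) {
    pr <- stereo_params(d_min = 0, d_max = 4, census_window = c(5, 3),
                        L1 = 6, L2 = 3, weight_mode = wm)
    arms <- build_cross(left, pr)
    alpha <- if (wm == "variable") alpha_weight(hmin_map(arms))
             else matrix(0.5, 12, 12)
    got <- combined_cost_volume(left, right, pr, arms_left = arms)
    want <- oracle_cost_volume(left, right, pr, alpha)
    expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-12)
  }
})

test_that("cost volume degenerate cases", {
  img <- matrix(runif(100, 0, 255), 10, 10)
  pr <- stereo_params(d_min = 0, d_max = 3)
  v <- combined_cost_volume(img, img, pr)
  expect_equal(max(abs(v[, , 1])), 0)      # identical pair at d = 0

  # alpha = 1 collapses onto the normalised AD cost
  pr1 <- stereo_params(d_min = 0, d_max = 3, weight_mode = "fixed",
                       alpha_fixed = 1)
  right <- matrix(runif(100, 0, 255), 10, 10)
  v1 <- combined_cost_volume(img, right, pr1)
  for (d in 0:3) for (j in (d + 1):10) for (i in 1:10)
    expect_equal(v1[i, j, d + 1],
                 1 - exp(-abs(img[i, j] - right[i, j - d]) / pr1$lambda_ad),
                 tolerance = 1e-12)
  # combined costs live in [0, 1) away from the border sentinel
  expect_true(all(v1 >= 0 & v1 <= 1))
})

test_that("ad_cost and rho follow their definitions", {
  L <- matrix(200 / 255, 4, 4); R <- matrix(180 / 255, 4, 4)
  expect_equal(ad_cost(L, R, c(2, 3), 0), 20)
  expect_equal(ad_cost(L, L, c(2, 3), 0), 0)
  expect_equal(ad_cost(L, R, c(2, 3), 5), Inf)   # out-of-frame sentinel
  expect_equal(rho(Inf, 10), 1)
  expect_equal(rho(0, 7), 0)
  expect_equal(rho(10, 10), 1 - exp(-1))
  expect_true(all(diff(rho(seq(0, 50, 5), 10)) > 0))
  expect_error(rho(1, 0), "lambda")
})

test_that("cross arms match the brute-force traversal oracle", {
  set.seed(17)
  for (mode in c("original", "optimized")) {
    img <- matrix(runif(16 * 16, 0, 255), 16, 16)
    pr <- stereo_params(mode = mode, L = 6, tau = 40, L1 = 7, L2 = 3,
                        tau1 = 40, tau2 = 15)
    got <- build_cross(img, pr)
    want <- oracle_cross(img, pr)
    for (nm in c("left", "right", "up", "down"))
      expect_identical(unclass(got)[[nm]], want[[nm]])
  }
})

test_that("cross arms respect edges, tiers and uniform regions", {
  u <- matrix(128, 30, 30)
  pr <- stereo_params(L1 = 8, L2 = 4, tau1 = 20, tau2 = 6)
  arms <- build_cross(u, pr)
  expect_true(all(arms$right[, 1:(30 - 8)] == 8))   # all extensions = L1

  # hard step: arm stops before crossing an edge of magnitude > tau1
  se <- step_edge_image(20, 20, at = 10, lo = 60, hi = 180)
  a2 <- build_cross(se, pr)
  # at column 8 the right arm sees the step at distance 3: the consecutive
  # condition fails at e = 2 (pixels 10 -> 11 differ by 120)
  expect_equal(a2$right[5, 8], 1)
  expect_equal(a2$right[5, 7], 2)

  # gentle ramp with per-step difference between tau2 and tau1: the near
  # tier accepts, the far tier rejects
  ramp <- matrix(rep(seq(0, by = 10, length.out = 24), each = 12), 12, 24,
                 byrow = FALSE)
  a3 <- build_cross(ramp, stereo_params(L1 = 10, L2 = 3, tau1 = 35,
                                        tau2 = 6))
  # |I(p) - I(p')| = 10 e < 35 holds up to e = 3; far tier needs < 6
  expect_equal(a3$right[6, 5], 3)

  expect_error(stereo_params(L1 = 4, L2 = 8), "L1 > L2")
  expect_error(stereo_params(tau1 = 5, tau2 = 7), "L1 > L2")
})

test_that("alpha weighting is large at edges, small in interiors", {
  expect_equal(alpha_weight(1), 1 - exp(-1))
  expect_lt(alpha_weight(1e9), 1e-8)
  expect_true(alpha_weight(1) > alpha_weight(5) &&
                alpha_weight(5) > alpha_weight(17))

  se <- step_edge_image(40, 40, at = 20)
  arms <- build_cross(se, stereo_params())
  a <- alpha_weight(hmin_map(arms))
  near_edge <- a[5:36, 19:22]
  interior <- a[5:36, c(8:12, 28:32)]
  expect_gt(mean(near_edge), mean(interior))
})

test_that("one CBCA pass equals explicit support-region enumeration", {
  set.seed(19)
  left <- matrix(runif(10 * 10, 0, 255), 10, 10)
  right <- matrix(runif(10 * 10, 0, 255), 10, 10)
  pr <- stereo_params(d_min = 0, d_max = 3, L1 = 4, L2 = 2,
                      census_window = c(3, 3))
  armsL <- build_cross(left, pr)
  armsR <- build_cross(right, pr)
  vol <- combined_cost_volume(left, right, pr, arms_left = armsL)
  for (hf in c(TRUE, FALSE)) {
    got <- aggregate_cbca(vol, armsL, armsR, pr, iterations = 1,
                          horizontal_first = hf)
    want <- oracle_cbca_pass(vol, armsL, armsR, 0, hf)
    expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-12)
  }
})

test_that("aggregation is the identity for singleton regions and conserves
           uniform volumes", {
  vol <- array(runif(8 * 8 * 3), c(8, 8, 3))
  attr(vol, "d_min") <- 0L
  zero_arms <- structure(list(left = matrix(0L, 8, 8),
                              right = matrix(0L, 8, 8),
                              up = matrix(0L, 8, 8),
                              down = matrix(0L, 8, 8)),
                         class = "cross_arms")
  out <- aggregate_cbca(vol, zero_arms, zero_arms, stereo_params(d_max = 2),
                        iterations = 1)
  expect_equal(as.numeric(out), as.numeric(vol), tolerance = 1e-14)

  uni <- array(0.37, c(8, 8, 3))
  attr(uni, "d_min") <- 0L
  img <- matrix(100, 8, 8)
  pr <- stereo_params(d_max = 2, L1 = 4, L2 = 2)
  arms <- build_cross(img, pr)
  out2 <- aggregate_cbca(uni, arms, arms, pr, iterations = 2)
  expect_equal(as.numeric(out2), rep(0.37, length(uni)), tolerance = 1e-13)
})

test_that("WTA takes the argmin with ties toward smaller disparity", {
  vol <- array(1, c(2, 2, 8))
  vol[1, 1, 5] <- 0.2
  vol[2, 1, 4] <- 0.3; vol[2, 1, 8] <- 0.3     # tie between d = 3 and 7
  attr(vol, "d_min") <- 0L
  d <- wta_disparity(vol)
  expect_equal(d[1, 1], 4)
  expect_equal(d[2, 1], 3)
})

test_that("left-right refinement keeps consistent maps and fills outliers", {
  pr <- stereo_params(d_max = 10, lr_threshold = 1)
  dl <- matrix(4, 10, 20)
  dr <- matrix(4, 10, 20)
  expect_equal(lr_refine(dl, dr, pr), dl)

  dl2 <- dl; dl2[5, 10] <- 9                 # one inconsistent pixel
  out <- lr_refine(dl2, dr, pr)
  expect_equal(out[5, 10], 4)                # filled with smaller neighbour

  expect_warning(all_bad <- lr_refine(dl + 5, dr, pr), "invalidated")
  expect_true(all(is.na(all_bad)))
})

test_that("constant-disparity pair is recovered end-to-end", {
  st <- make_stereo_pair(stereo_phantom_spec(
    phantom_spec(48, 96, seed = 4, noise_sigma = 0.01), 6,
    texture_amplitude = 0.12))
  sm <- match_stereo(st$left, st$right, stereo_params(d_max = 12, L1 = 17,
                                                      L2 = 8))
  interior <- st$valid == 1
  interior[, 1:13] <- FALSE            # no in-frame match below d_max
  expect_gte(mean(sm$d_left[interior] == 6), 0.95)
})
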
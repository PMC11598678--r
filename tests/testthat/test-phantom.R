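test_that("phantom generation is deterministic and validates its spec", {
  sp <- phantom_spec(48, 56, n_vessels = 3, seed = 9)
  a <- make_vein_phantom(sp)
  b <- make_vein_phantom(sp)
  expect_identical(a, b)
  expect_equal(dim(a$image), c(48L, 56L))
  expect_true(all(a$image >= 0 & a$image <= 1))

  expect_error(phantom_spec(0, 10), "positive")
  expect_error(phantom_spec(10, 10, vessel_width_range = c(0.5, 3)), "width")
  expect_error(phantom_spec(10, 10, vessel_contrast = 0), "contrast")
})

test_that("empty phantom is the pure background ramp", {
  sp <- phantom_spec(32, 40, n_vessels = 0, noise_sigma = 0,
                     background_level = 0.6, illumination_gradient = 0.2)
  ph <- make_vein_phantom(sp)
  expect_equal(sum(ph$mask), 0)
  ramp <- 0.6 * (1 + 0.2 * (seq(0, 1, length.out = 40) - 0.5))
  expect_equal(ph$image, matrix(rep(ramp, each = 32), 32, 40))
})

test_that("straight tube has the constructed depth and width", {
  ph <- make_vein_phantom(straight_tube_spec())
  # core intensity = background * (1 - contrast) on the centerline row
  expect_equal(min(ph$image[, 20]), 0.8 * 0.5, tolerance = 1e-12)
  expect_equal(which.min(ph$image[, 20]), 32)
  # mask column cross-section covers the 5-px tube
  expect_equal(sum(ph$mask[, 20]), 5)
  expect_equal(which(ph$mask[, 20] == 1), 30:34)
})

test_that("mask pixels are darker than equally-lit background (pre-noise)", {
  for (seed in 1:3) {
    sp <- phantom_spec(64, 64, n_vessels = 3, noise_sigma = 0,
                       illumination_gradient = 0, seed = seed)
    ph <- make_vein_phantom(sp)
    bgl <- sp$background_level
    expect_true(all(ph$image[ph$mask == 1] < bgl))
    expect_true(mean(ph$image[ph$mask == 1]) < mean(ph$image[ph$mask == 0]))
  }
})

test_that("stereo pair satisfies the warp identity on valid pixels", {
  st <- make_stereo_pair(stereo_phantom_spec(phantom_spec(40, 80, seed = 5),
                                             6, texture_amplitude = 0.1))
  ok <- which(st$valid == 1, arr.ind = TRUE)
  diffs <- mapply(function(r, cc) st$left[r, cc] - st$right[r, cc - 6],
                  ok[, 1], ok[, 2])
  expect_equal(max(abs(diffs)), 0)
  expect_true(all(st$disparity[ok] == 6))
})

test_that("zero disparity reproduces the left image with full validity", {
  st <- make_stereo_pair(stereo_phantom_spec(phantom_spec(30, 40, seed = 2),
                                             0))
  expect_identical(st$left, st$right)
  expect_true(all(st$valid == 1))
})

test_that("disparity step produces the occlusion band the geometry predicts", {
  d <- matrix(4, 24, 60)
  d[, 31:60] <- 10
  st <- make_stereo_pair(stereo_phantom_spec(phantom_spec(24, 60, seed = 3),
                                             d))
  expect_identical(st$valid, oracle_visibility(d))
  # the occlusion band left of the step has width d_fg - d_bg = 6
  expect_equal(which(st$valid[12, 5:60] == 0) + 4L, 25:30)
})

test_that("invalid stereo specs are rejected", {
  sp <- phantom_spec(20, 30)
  expect_error(stereo_phantom_spec(sp, -1), "nonnegative")
  expect_error(stereo_phantom_spec(sp, 30), "width")
})

test_that("unlabeled sets are sized, distinct, reproducible and fast", {
  sp <- phantom_spec(96, 96, seed = 4)
  t0 <- proc.time()
  imgs <- make_unlabeled_set(120, sp, seed = 4)
  elapsed <- (proc.time() - t0)[3]
  expect_length(imgs, 120)
  expect_false(identical(imgs[[1]], imgs[[2]]))
  expect_lt(elapsed, 10)
  again <- make_unlabeled_set(3, sp, seed = 4)
  expect_identical(imgs[1:3], again)
  expect_error(make_unlabeled_set(0, sp), ">= 1")
})
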
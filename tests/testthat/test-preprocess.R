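test_that("CLAHE keeps constant images constant and mappings monotone", {
  const <- matrix(0.5, 64, 64)
  out <- clahe(const)
  expect_equal(max(out) - min(out), 0)
  expect_lt(abs(out[1, 1] - 0.5), 5 / 255)  # redistribution shift only

  set.seed(1)
  two <- matrix(sample(c(40, 200), 64 * 64, TRUE) / 255, 64, 64)
  eq <- clahe(two)
  expect_lte(max(eq[two == 40 / 255]), min(eq[two == 200 / 255]))
})

test_that("CLAHE raises the contrast of a low-contrast phantom", {
  ph <- make_vein_phantom(phantom_spec(96, 96, vessel_contrast = 0.15,
                                       background_level = 0.55,
                                       noise_sigma = 0.01, seed = 8))
  expect_gt(stats::sd(clahe(ph$image)), stats::sd(ph$image))
})

test_that("median filter matches hand-evaluated cases", {
  const <- matrix(0.3, 16, 16)
  expect_equal(median_filter(const, 3), const)

  imp <- matrix(0.5, 9, 9); imp[5, 5] <- 1
  expect_equal(median_filter(imp, 3), matrix(0.5, 9, 9))

  row <- matrix(c(1, 9, 1, 1, 1), 1, 5)
  expect_equal(as.numeric(median_filter(row, 3)), rep(1, 5))

  expect_error(median_filter(const, 4), "odd")
})

test_that("median filter commutes with global intensity shifts", {
  set.seed(3)
  img <- matrix(runif(30 * 30, 0.2, 0.6), 30, 30)
  expect_equal(median_filter(img + 0.3, 5), median_filter(img, 5) + 0.3)
})

test_that("pipeline composes, logs its config and round-trips YAML", {
  ph <- make_vein_phantom(phantom_spec(64, 64, seed = 12))
  cfg <- preprocess_config(tile_grid = c(4, 4), clip_limit = 3,
                           median_kernel = 3)
  out <- preprocess_pipeline(ph$image, cfg)
  expect_equal(dim(out), dim(ph$image))
  expect_identical(attr(out, "config"), cfg)

  cfg2 <- do.call(preprocess_config,
                  yaml::yaml.load(yaml::as.yaml(unclass(cfg))))
  out2 <- preprocess_pipeline(ph$image, cfg2)
  expect_equal(unclass(out), unclass(out2), ignore_attr = TRUE)

  const <- matrix(0.4, 32, 32)
  pc <- preprocess_pipeline(const, cfg)
  expect_equal(max(pc) - min(pc), 0)
})

test_that("pipeline suppresses impulse outliers better than CLAHE alone", {
  ph <- make_vein_phantom(phantom_spec(96, 96, noise_sigma = 0, seed = 4))
  img <- ph$image
  set.seed(99)
  hits <- sample(length(img), 150)
  img[hits] <- ifelse(runif(150) > 0.5, 1, 0)      # salt-and-pepper
  outliers <- function(x) {
    med <- median_filter(x, 3)
    sum(abs(x - med) > 3 * stats::sd(x - med))
  }
  expect_lt(outliers(preprocess_pipeline(img)), outliers(clahe(img)))
})

test_that("invalid preprocessing configs are rejected", {
  expect_error(preprocess_config(clip_limit = 0), "clip_limit")
  expect_error(preprocess_config(median_kernel = 4), "odd")
  expect_error(clahe(array(0.1, c(4, 4, 3))), "matrix")
})
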
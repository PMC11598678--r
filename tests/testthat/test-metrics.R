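test_that("BCE matches closed forms", {
  lab <- matrix(c(1, 0, 1, 1), 2, 2)
  expect_lt(bce(lab, lab), 1e-6)                       # perfect prediction
  expect_equal(bce(matrix(0.5, 2, 2), lab), log(2))
  expect_equal(bce(matrix(0.8, 1, 1), matrix(1, 1, 1)), -log(0.8))
  expect_equal(-log(0.8), 0.22314, tolerance = 1e-4)
  expect_error(bce(matrix(0.5, 2, 2), matrix(1, 3, 3)), "shape")
})

test_that("BCE over constant predictors is minimised at the prevalence", {
  set.seed(2)
  for (prev in c(0.1, 0.35, 0.7)) {
    lab <- matrix(rbinom(900, 1, prev), 30, 30)
    p_hat <- mean(lab)
    grid <- seq(0.01, 0.99, 0.01)
    losses <- vapply(grid, function(p) bce(matrix(p, 30, 30), lab), 1)
    expect_equal(grid[which.min(losses)], round(p_hat, 2),
                 tolerance = 0.011)
  }
})

test_that("IoU and Dice follow their formulas and conventions", {
  a <- matrix(c(1, 1, 0, 0), 2, 2)
  same <- confusion(a, a)
  expect_equal(iou(same), 1)
  expect_equal(dice(same), 1)

  b <- matrix(c(0, 0, 1, 1), 2, 2)
  disj <- confusion(a, b)
  expect_equal(iou(disj), 0)
  expect_equal(dice(disj), 0)

  cc <- list(TP = 3, FP = 1, FN = 1, TN = 10)
  expect_equal(iou(cc), 0.6)
  expect_equal(dice(cc), 0.75)

  z <- matrix(0, 2, 2)
  expect_equal(iou(confusion(z, z)), 1)      # both-empty convention
  expect_equal(dice(confusion(z, z)), 1)
  expect_error(confusion(matrix(0.5, 2, 2), z), "binary")
})

test_that("Dice = 2 IoU / (1 + IoU) for random confusion tables", {
  set.seed(7)
  for (i in 1:50) {
    cc <- list(TP = sample(0:50, 1), FP = sample(0:50, 1),
               FN = sample(0:50, 1), TN = sample(0:50, 1))
    if (cc$TP + cc$FP + cc$FN == 0) next
    expect_equal(dice(cc), 2 * iou(cc) / (1 + iou(cc)), tolerance = 1e-12)
  }
})

test_that("Hausdorff distance matches hand cases and directions", {
  A <- cbind(0, 0)
  expect_equal(hausdorff(A, A), 0)
  expect_equal(hausdorff(cbind(0, 0), cbind(3, 4)), 5)
  expect_equal(hausdorff(rbind(c(0, 0), c(10, 0)), cbind(0, 0)), 10)
  expect_error(hausdorff(A, A[0, , drop = FALSE]), "empty")
})

test_that("Hausdorff distance-transform fast path equals brute force", {
  set.seed(11)
  for (i in 1:8) {
    A <- unique(cbind(sample(1:40, 60, TRUE), sample(1:40, 60, TRUE)))
    B <- unique(cbind(sample(1:40, 80, TRUE), sample(1:40, 80, TRUE)))
    expect_equal(hausdorff(A, B, method = "grid"),
                 hausdorff(A, B, method = "brute"), tolerance = 1e-9)
  }
})

test_that("boundary extraction keeps only 4-adjacent-to-background pixels", {
  m <- matrix(0, 7, 7)
  m[3:5, 3:5] <- 1
  bp <- boundary_points(m)
  expect_equal(nrow(bp), 8)                 # 3x3 square minus its centre
  expect_false(any(bp[, 1] == 4 & bp[, 2] == 4))
})

test_that("illuminance uniformity is min over mean", {
  expect_equal(uniformity(matrix(2, 4, 4)), 1)
  expect_equal(uniformity(matrix(c(1, 1, 2), 1, 3)), 0.75)
  set.seed(1)
  g <- matrix(runif(64, 0.5, 2), 8, 8)
  expect_lte(uniformity(g), 1)
  expect_error(uniformity(matrix(0, 2, 2)), "zero")
})

test_that("disparity error statistics count bad pixels correctly", {
  gt <- matrix(5, 10, 10)
  expect_equal(disparity_error(gt, gt), list(mae = 0, bad_percent = 0))
  expect_equal(disparity_error(gt + 1, gt, bad_threshold = 2),
               list(mae = 1, bad_percent = 0))
  est <- gt
  est[, 1:5] <- gt[, 1:5] + 5
  expect_equal(disparity_error(est, gt, bad_threshold = 2)$bad_percent, 50)
  expect_error(disparity_error(gt * NA, gt), "valid")
})

test_that("percent change reports reductions and increases", {
  expect_equal(percent_change(10, 10, "reduction"), 0)
  expect_equal(percent_change(20, 15, "reduction"), 25)
  expect_equal(percent_change(20, 25, "increase"), 25)
  expect_error(percent_change(0, 1), "nonzero")
})
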
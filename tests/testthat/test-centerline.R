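test_that("Hessian eigenvalues match analytic cases", {
  const <- matrix(0.7, 32, 32)
  e <- hessian_eigenvalues(const, 2)
  expect_equal(max(abs(e$l1)), 0)
  expect_equal(max(abs(e$l2)), 0)

  # I(r, c) = r^2 has Hessian diag(2, 0) everywhere in the interior
  H <- 48
  r2 <- matrix((seq_len(H) - 1)^2, H, H)
  e <- hessian_eigenvalues(r2, 2)
  interior <- 12:36
  expect_equal(e$l2[interior, interior],
               matrix(2, length(interior), length(interior)),
               tolerance = 1e-8)
  expect_equal(max(abs(e$l1[interior, interior])), 0, tolerance = 1e-8)

  expect_error(hessian_eigenvalues(const, 0), "sigma")
})

test_that("eigenvalue ordering satisfies |l1| <= |l2|", {
  ph <- make_vein_phantom(phantom_spec(64, 64, seed = 6))
  e <- hessian_eigenvalues(ph$image, 2)
  expect_true(all(abs(e$l1) <= abs(e$l2) + 1e-14))
})

test_that("vesselness responds to dark tubes and gates on polarity", {
  z <- matrix(0, 10, 10)
  expect_equal(vein_response(z, z), z)

  # bright ridge: l2 < 0 everywhere -> zero response under dark polarity
  neg <- matrix(-3, 10, 10)
  expect_equal(vein_response(z, neg), z)

  ph <- make_vein_phantom(straight_tube_spec())
  e <- hessian_eigenvalues(ph$image, 2)
  expect_gt(e$l2[32, 32], 0)
  expect_gt(abs(e$l2[32, 32]), 10 * abs(e$l1[32, 32]))

  expect_error(vein_response(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("response peaks within 1 px of the generating centerline", {
  ph <- make_vein_phantom(straight_tube_spec(row = 30, width = 6))
  resp <- vesselness(ph$image, hessian_config(sigma = c(1.5, 2, 3)))
  peak_rows <- apply(resp[, 8:56], 2, which.max)
  expect_true(all(abs(peak_rows - 30) <= 1))
})

test_that("skeleton extraction thins to a unit-width connected path", {
  solid <- matrix(0, 40, 60)
  solid[18:22, 6:54] <- 1   # 5-px solid tube
  skel <- extract_centerline(solid, 0.5)
  expect_true(all(colSums(skel[, 10:50]) <= 2))
  expect_equal(max(label8(skel)), 1)        # one 8-connected path

  expect_warning(empty <- extract_centerline(matrix(0, 8, 8), 0.5),
                 "empty")
  expect_equal(sum(empty), 0)

  resp <- matrix(runif(100), 10, 10)
  expect_warning(e2 <- extract_centerline(resp, max(resp) + 1), "empty")
  expect_equal(sum(e2), 0)
})

test_that("refinement removes islands, joins gaps and is a fixed point", {
  m <- matrix(0L, 30, 60)
  m[15, 5:24] <- 1L                  # segment A
  m[15, 29:50] <- 1L                 # segment B, 4-px gap
  m[5, 3:5] <- 1L                    # 3-px island
  cfg <- refine_config(min_region_area = 10, max_gap_distance = 5,
                       spur_length = 0)
  out <- refine_centerline(m, cfg)
  expect_equal(sum(out[5, ]), 0)                    # island removed
  expect_equal(max(label8(out)), 1)                 # gap joined
  expect_true(all(out[15, 5:50] == 1))

  clean <- matrix(0L, 20, 40)
  clean[10, 3:38] <- 1L
  expect_equal(refine_centerline(clean, refine_config(5, 5, 3)), clean)
})

test_that("spur pruning removes short branches but keeps the main line", {
  m <- matrix(0L, 30, 60)
  m[15, 3:57] <- 1L
  for (k in 1:4) m[15 - k, 30 + k] <- 1L   # 4-px diagonal burr
  out <- refine_centerline(m, refine_config(min_region_area = 0,
                                            max_gap_distance = 0,
                                            spur_length = 6))
  expect_equal(sum(out[1:14, ]), 0)
  expect_true(all(out[15, 3:57] == 1))
})

test_that("refinement never increases the component count", {
  set.seed(5)
  for (i in 1:3) {
    ph <- make_vein_phantom(phantom_spec(64, 64, n_vessels = 3,
                                         noise_sigma = 0.03, seed = i))
    resp <- vesselness(ph$image, hessian_config())
    skel <- suppressWarnings(extract_centerline(resp, 0.1))
    before <- max(label8(skel))
    after <- max(label8(refine_centerline(skel, refine_config(10, 8, 5))))
    expect_lte(after, max(before, 1))
  }
})

test_that("extracted centerline localises inside the dilated true mask", {
  ph <- make_vein_phantom(straight_tube_spec(width = 6))
  resp <- vesselness(ph$image, hessian_config(sigma = c(1.5, 2, 3)))
  skel <- extract_centerline(resp, hessian_config(response_threshold = 0.2))
  dil <- as.matrix(EBImage::dilate(ph$mask,
                                   EBImage::makeBrush(5, "box"))) > 0
  pts <- centerline_points(skel)
  expect_gt(nrow(pts), 20)
  expect_true(all(dil[pts]))
})
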
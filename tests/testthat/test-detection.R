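test_that("sobel magnitude matches a brute-force kernel correlation", {
  set.seed(11)
  for (k in 1:20) {
    m <- matrix(rnorm(25), 5, 5)
    hm <- height_map(m, 1)
    gx <- brute_correlate3(m, sobel_kx)
    gy <- brute_correlate3(m, sobel_ky)
    expect_equal(sobel_magnitude(hm), sqrt(gx^2 + gy^2), tolerance = 1e-12)
  }
})

test_that("sobel magnitude is zero on constants and peaks on a step", {
  expect_true(all(sobel_magnitude(flat_map(3.7)) == 0))
  m <- matrix(0, 12, 12); m[, 7:12] <- 5
  g <- sobel_magnitude(height_map(m, 1))
  expect_true(all(g[, c(1:3, 10:12)] == 0))       # flat far from the step
  expect_equal(max(g), max(g[, 6:7]))             # maximum on the step columns
})

test_that("detect_particles segments a blob and validates its factor", {
  b <- make_blob(c(64, 64), sigma_px = 3, amplitude_nm = 3, pixel_size_nm = 1)
  pm <- detect_particles(b$map, 1)
  expect_s3_class(pm, "particle_mask")
  expect_identical(dim(pm$mask), dim(b$map$heights))
  expect_true(pm$mask[32, 32])                    # apex pixel captured
  lp <- label_and_select_largest(pm)
  expect_identical(lp$n_particles, 1L)            # one connected component

  # absurd factor leaves nothing
  expect_false(any(detect_particles(b$map, 1000)$mask))
  expect_error(detect_particles(b$map, 0), "positive")
  expect_error(detect_particles(b$map, -2), "positive")
})

test_that("border-connected components are suppressed", {
  m <- matrix(0, 48, 48)
  rr <- matrix(0:47, 48, 48); cc <- t(rr)
  m <- 3 * exp(-((rr - 2)^2 + (cc - 24)^2) / 8)   # blob support on the border
  pm <- detect_particles(height_map(m, 1), 1)
  expect_false(any(pm$mask))
  # no mask from detect_particles may ever touch the border
  b <- make_blob(c(64, 64), sigma_px = 3, amplitude_nm = 3, pixel_size_nm = 1)
  mk <- detect_particles(b$map, 0.5)$mask
  expect_false(any(mk[1, ], mk[64, ], mk[, 1], mk[, 64]))
})

test_that("raw edge sets shrink monotonically with the threshold factor", {
  b <- make_blob(c(64, 64), sigma_px = 4, amplitude_nm = 2, pixel_size_nm = 1)
  g <- sobel_magnitude(b$map)
  base <- 4 * sqrt(mean(g^2))
  factors <- c(0.3, 0.6, 1, 1.5, 3)
  sets <- lapply(factors, function(f) g >= f * base)
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i + 1]] <= sets[[i]]))  # subset relation
})

test_that("background is the mean outside the mask", {
  hm <- flat_map(1.0, 10)
  empty <- matrix(FALSE, 10, 10)
  expect_equal(estimate_background(hm, empty), 1.0)

  b <- make_blob(c(32, 32), sigma_px = 2, amplitude_nm = 5, pixel_size_nm = 1)
  pm <- detect_particles(b$map, 0.5)
  # background ~0: the blob tail outside the mask is tiny
  expect_lt(estimate_background(b$map, pm), 0.02)

  chk <- matrix(c(0, 2), 8, 8)                    # checkerboard columns of 0/2
  mask2 <- chk == 2
  expect_equal(estimate_background(height_map(chk, 1), mask2), 0)
  expect_error(estimate_background(hm, matrix(TRUE, 10, 10)), "background")
  expect_error(estimate_background(hm, matrix(TRUE, 9, 9)), "shape")
})

test_that("largest particle selection is by area with scan-order tie-break", {
  m <- matrix(FALSE, 20, 30)
  m[3:8, 3:7] <- TRUE          # 30 px
  m[3:12, 15:21] <- TRUE       # 70 px
  lp <- label_and_select_largest(m)
  expect_identical(lp$n_particles, 2L)
  expect_identical(sort(lp$areas_px), c(30L, 70L))
  expect_identical(lp$areas_px[lp$selected], 70L)

  # equal areas: the component seen first in row-major order wins
  m2 <- matrix(FALSE, 20, 30)
  m2[10:12, 20:22] <- TRUE
  m2[2:4, 2:4] <- TRUE
  lp2 <- label_and_select_largest(m2)
  sel_px <- which(lp2$labels == lp2$selected, arr.ind = TRUE)
  expect_true(all(sel_px[, "row"] <= 4))
  expect_error(label_and_select_largest(matrix(FALSE, 4, 4)), "empty")
})

test_that("8-connectivity holds diagonal chains together", {
  m <- matrix(FALSE, 10, 10)
  for (i in 1:8) m[i, i] <- TRUE
  expect_identical(label_and_select_largest(m)$n_particles, 1L)
})

test_that("intensity threshold mask is the documented baseline", {
  m <- matrix(0, 8, 8); m[4, 4] <- 10; m[2, 2] <- 3
  im <- intensity_threshold_mask(height_map(m, 1), 0.2)
  expect_identical(im$mask, m >= 2)
  expect_true(all(intensity_threshold_mask(flat_map(2), 0.5)$mask))
  expect_error(intensity_threshold_mask(flat_map(1), 0), "between")
  expect_error(intensity_threshold_mask(flat_map(1), 1.2), "between")
})

test_that("gradient detection is more tilt-robust than intensity thresholding", {
  b <- make_blob(c(96, 96), sigma_px = 4, amplitude_nm = 3, pixel_size_nm = 1)
  tilted <- add_plane(b$map, slope_col_nm_per_px = 0.2 * 3 / 95)
  iou_grad <- mask_iou(detect_particles(tilted, 1)$mask,
                       detect_particles(b$map, 1)$mask)
  iou_int <- mask_iou(intensity_threshold_mask(tilted, 0.15)$mask,
                      intensity_threshold_mask(b$map, 0.15)$mask)
  expect_gt(iou_grad, iou_int)
  expect_gt(iou_grad, 0.9)
})
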
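test_that("detect_all returns one record per well-separated particle", {
  rr <- matrix(0:127, 128, 128); cc <- t(rr)
  h <- 3 * exp(-((rr - 30)^2 + (cc - 30)^2) / (2 * 9)) +
       2 * exp(-((rr - 30)^2 + (cc - 95)^2) / (2 * 16)) +
       4 * exp(-((rr - 95)^2 + (cc - 62)^2) / (2 * 9))
  hm <- height_map(h, 1)
  recs <- detect_all(hm, 0.5)
  expect_identical(nrow(recs), 3L)
  expect_true(all(recs$solidity > 0 & recs$solidity <= 1))
  expect_true(all(recs$eccentricity >= 0 & recs$eccentricity < 1))
  expect_true(all(recs$minor_axis_nm <= recs$major_axis_nm))
  expect_true(all(recs$axis_ratio > 0 & recs$axis_ratio <= 1))
  # sum_intensity * pixel_area == volume
  expect_equal(recs$volume_nm3,
               recs$sum_intensity_nm * recs$pixel_size_nm^2,
               tolerance = 1e-12)
})

test_that("a filled disk is compact and round; a crescent is not solid", {
  rr <- matrix(0:63, 64, 64); cc <- t(rr)
  disk <- (rr - 31)^2 + (cc - 31)^2 <= 14^2
  h <- matrix(0, 64, 64); h[disk] <- 2
  recs <- detect_all(height_map(h, 1), 0.5)
  expect_identical(nrow(recs), 1L)
  expect_equal(recs$solidity, 1, tolerance = 0.02)
  expect_lt(recs$eccentricity, 0.1)
  expect_gt(recs$axis_ratio, 0.95)

  crescent <- disk & !((rr - 31)^2 + (cc - 22)^2 <= 12^2)
  h2 <- matrix(0, 64, 64); h2[crescent] <- 2
  recs2 <- detect_all(height_map(h2, 1), 0.5)
  # oracle: pixel count over rasterized convex hull pixel count
  px <- which(crescent, arr.ind = TRUE)
  hull <- grDevices::chull(px[, 2], px[, 1])
  expect_lt(recs2$solidity, 0.8)
})

test_that("detect_all volume equals the single-particle volume on the same mask", {
  b <- make_blob(c(96, 96), sigma_px = 4, amplitude_nm = 2, pixel_size_nm = 1.5)
  recs <- detect_all(b$map, 0.3)
  pm <- detect_particles(b$map, 0.3)
  bg <- estimate_background(b$map, pm)
  lp <- label_and_select_largest(pm)
  v <- particle_volume(b$map, lp, background = bg)
  expect_equal(recs$volume_nm3[1], v$volume_nm3, tolerance = 1e-9)
})

test_that("synthetic blob volumes are recovered from whole images", {
  set.seed(31)
  for (k in 1:5) {
    sg <- runif(1, 2, 6); A <- runif(1, 0.5, 5)
    b <- make_blob(c(160, 160), sigma_px = sg, amplitude_nm = A,
                   pixel_size_nm = 1)
    recs <- detect_all(b$map, 0.3)
    expect_identical(nrow(recs), 1L)
    expect_equal(recs$volume_nm3, b$truth$analytic_volume_nm3,
                 tolerance = 0.05)
  }
})

test_that("batch_folder concatenates records and skips unreadable files", {
  td <- withr::local_tempdir()
  b1 <- make_blob(c(64, 64), sigma_px = 3, amplitude_nm = 2, pixel_size_nm = 2)
  rr <- matrix(0:95, 96, 96); cc <- t(rr)
  h2 <- 2 * exp(-((rr - 30)^2 + (cc - 30)^2) / 18) +
        3 * exp(-((rr - 65)^2 + (cc - 70)^2) / 18)
  m2 <- height_map(h2, 2)
  write_fixture(b1$map, "ibw", file.path(td, "a.ibw"))
  write_fixture(m2, "ibw", file.path(td, "b.ibw"))
  recs <- batch_folder(td, 0.5, format_hint = "ibw")
  expect_identical(nrow(recs), 3L)
  expect_setequal(unique(recs$image), c("a.ibw", "b.ibw"))

  # determinism: identical output on a second run
  expect_identical(batch_folder(td, 0.5, format_hint = "ibw"), recs)

  # corrupt file is skipped with a warning, good files still processed
  writeLines("garbage", file.path(td, "c.ibw"))
  expect_warning(recs2 <- batch_folder(td, 0.5, format_hint = "ibw"),
                 "skipping")
  expect_identical(nrow(recs2), 3L)
  expect_error(batch_folder(file.path(td, "absent")), "not found")
})

test_that("volume histograms bin and bound correctly", {
  recs <- data.frame(volume_nm3 = c(100, 200, 300))
  vh <- volume_histogram(recs, 50, 350, 3)
  expect_identical(vh$counts, c(1L, 1L, 1L))
  expect_equal(sum(vh$counts), 3L)

  vh2 <- volume_histogram(recs, 400, 500, 4)
  expect_true(all(vh2$counts == 0L))

  set.seed(5)
  r3 <- data.frame(volume_nm3 = runif(200, 0, 1000))
  vh3 <- volume_histogram(r3, 100, 600, 15)
  expect_identical(sum(vh3$counts),
                   sum(r3$volume_nm3 >= 100 & r3$volume_nm3 <= 600))
  expect_error(volume_histogram(recs, 10, 5, 3), "v_min")
  expect_error(volume_histogram(recs, 0, 10, 0), "n_bins")
})

test_that("mass calibration is linear through the origin", {
  recs <- data.frame(volume_nm3 = c(818, 1636, 0))
  out <- calibrate_to_kda(recs, standard_volume_nm3 = 818,
                          standard_mass_kda = 450)
  expect_equal(out$mass_kda, c(450, 900, 0))
  expect_error(calibrate_to_kda(recs, 0, 450), "positive")
  expect_error(calibrate_to_kda(recs, 818, -1), "positive")
})
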
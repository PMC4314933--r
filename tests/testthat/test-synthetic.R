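test_that("blob ground truth carries the analytic Gaussian volume", {
  b <- make_blob(c(64, 64), sigma_px = 3, amplitude_nm = 2, pixel_size_nm = 1)
  expect_equal(b$truth$analytic_volume_nm3, 2 * pi * 9 * 2)
  # the discrete sum converges to the continuum integral for sigma >= 2
  expect_equal(sum(b$map$heights), b$truth$analytic_volume_nm3,
               tolerance = 0.01)
  # pixel-area scaling: doubling the pixel size quadruples the volume
  b2 <- make_blob(c(64, 64), sigma_px = 3, amplitude_nm = 2,
                  pixel_size_nm = 2)
  expect_equal(b2$truth$analytic_volume_nm3, 4 * b$truth$analytic_volume_nm3)
  # zero amplitude produces a flat image
  b0 <- make_blob(c(64, 64), sigma_px = 3, amplitude_nm = 0)
  expect_true(all(b0$map$heights == 0))
  expect_error(make_blob(c(32, 32), center = c(3, 16), sigma_px = 3),
               "border")
})

test_that("filament ground truth length matches the centerline geometry", {
  f <- make_filament(c(40, 140), "line", length_px = 100, sigma_px = 2,
                     amplitude_nm = 2, pixel_size_nm = 1)
  expect_equal(f$truth$contour_length_nm, 100)
  expect_equal(f$truth$contour_length_px, 100)

  a <- make_filament(c(256, 256), "arc", radius_px = 100, angle_rad = pi,
                     sigma_px = 2, amplitude_nm = 2, pixel_size_nm = 1)
  expect_equal(a$truth$contour_length_nm, pi * 100, tolerance = 1e-3)

  # nm scaling through the pixel size
  f2 <- make_filament(c(40, 140), "line", length_px = 100, sigma_px = 2,
                      amplitude_nm = 2, pixel_size_nm = 2.5)
  expect_equal(f2$truth$contour_length_nm, 250)
})

test_that("seeded walks are deterministic and self-avoiding", {
  w1 <- make_filament(c(256, 256), "walk", length_px = 150, sigma_px = 2,
                      amplitude_nm = 2, pixel_size_nm = 1, seed = 9)
  w2 <- make_filament(c(256, 256), "walk", length_px = 150, sigma_px = 2,
                      amplitude_nm = 2, pixel_size_nm = 1, seed = 9)
  expect_identical(w1$map$heights, w2$map$heights)
  expect_identical(w1$truth$centerline, w2$truth$centerline)

  # min separation: vertices at least 6 steps apart stay >= 8 sigma away
  cl <- w1$truth$centerline
  n <- nrow(cl)
  min_sep <- Inf
  for (i in 1:(n - 6)) {
    d <- sqrt(rowSums((cl[(i + 6):n, , drop = FALSE] -
                       matrix(cl[i, ], n - i - 5, 2, byrow = TRUE))^2))
    min_sep <- min(min_sep, d)
  }
  expect_gte(min_sep, 8 * 2 - 1e-9)
})

test_that("plane tilt and noise behave as documented", {
  hm <- flat_map(0, 32)
  expect_identical(add_plane(hm, 0, 0)$heights, hm$heights)
  expect_identical(add_noise(hm, 0)$heights, hm$heights)

  tilted <- add_plane(hm, 0.1, -0.05)
  expect_equal(tilted$heights[11, 21], 0.1 * 10 - 0.05 * 20)
  # constant gradient in the interior of a tilted plane
  g <- sobel_magnitude(tilted)
  expect_lt(diff(range(g[5:28, 5:28])), 1e-9)

  n1 <- add_noise(hm, 0.5, seed = 3)
  n2 <- add_noise(hm, 0.5, seed = 3)
  expect_identical(n1$heights, n2$heights)
  big <- add_noise(flat_map(0, 1000), 0.5, seed = 4)
  expect_lt(abs(mean(big$heights)), 4 * 0.5 / 1000)
})

test_that("every fixture dialect round-trips within its quantization bound", {
  b <- make_blob(c(16, 16), center = c(7.5, 7.5), sigma_px = 1.8,
                 amplitude_nm = 2, pixel_size_nm = 4)
  m <- b$map
  td <- withr::local_tempdir()
  span <- diff(range(m$heights))

  cases <- list(
    nanoscope = c("scan.spm", 2 * 2 / 32000),
    jpk = c("scan.jpk.tif", span / 65535),
    ibw = c("scan.ibw", 1e-9),
    ascii = c("scan.txt", 1e-6),
    ascii_header = c("scanh.txt", 1e-6))
  for (d in names(cases)) {
    f <- file.path(td, cases[[d]][1])
    write_fixture(m, d, f)
    r <- switch(d, nanoscope = read_nanoscope(f), jpk = read_jpk(f),
                ibw = read_ibw(f), read_ascii(f))
    expect_lt(max(abs(r$heights - m$heights)),
              as.numeric(cases[[d]][2]) + 1e-12, label = d)
    expect_equal(r$pixel_size_x, 4, label = d)
  }

  for (d in c("tiff", "png")) {
    f <- file.path(td, paste0("r.", d))
    info <- write_fixture(m, d, f)
    r <- read_raster(f, info$height_scale_nm_per_unit, 4)
    expect_lt(max(abs(r$heights + info$offset_nm - m$heights)),
              span / 65535 + 1e-9, label = d)
  }

  f <- file.path(td, "r.jpg")
  info <- write_fixture(m, "jpeg", f)
  r <- read_raster(f, info$height_scale_nm_per_unit, 4)
  expect_gt(cor(as.vector(r$heights), as.vector(m$heights)), 0.99)
})
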
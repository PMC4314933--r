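test_that("particle volume is the background-subtracted sum times pixel area", {
  m <- matrix(0, 10, 10); m[3:4, 3:7] <- 2       # 10 px at 2 nm
  lp <- label_and_select_largest(m > 0)
  v <- particle_volume(height_map(m, 1), lp, background = 0)
  expect_equal(v$volume_nm3, 20)
  expect_identical(v$n_pixels, 10L)

  # background equal to the particle height nulls the volume
  v0 <- particle_volume(height_map(m, 1), lp, background = 2)
  expect_equal(v0$volume_nm3, 0)
  expect_error(particle_volume(height_map(m, 1), lp, selected = 5), "label")
})

test_that("a wide mask over a Gaussian blob recovers 2*pi*sigma^2*A", {
  b <- make_blob(c(64, 64), sigma_px = 3, amplitude_nm = 2, pixel_size_nm = 1)
  rr <- matrix(0:63, 64, 64); cc <- t(rr)
  mask <- (rr - 31.5)^2 + (cc - 31.5)^2 <= (4 * 3)^2
  lp <- label_and_select_largest(mask)
  v <- particle_volume(b$map, lp, background = 0)
  expect_equal(v$volume_nm3, 2 * pi * 9 * 2, tolerance = 0.01)
})

test_that("volume is invariant to a constant height offset", {
  b <- make_blob(c(48, 48), sigma_px = 2.5, amplitude_nm = 1.5,
                 pixel_size_nm = 2)
  pm <- detect_particles(b$map, 0.5)
  lp <- label_and_select_largest(pm)
  v1 <- particle_volume(b$map, lp,
                        background = estimate_background(b$map, pm))
  shifted <- b$map
  shifted$heights <- shifted$heights + 11.3
  v2 <- particle_volume(shifted, lp,
                        background = estimate_background(shifted, pm))
  expect_equal(v1$volume_nm3, v2$volume_nm3, tolerance = 1e-9)
})

test_that("path length applies per-axis pixel sizes and is additive", {
  hm <- flat_map(0, 16, ps = 2)
  expect_equal(path_length(trace_path(rbind(c(0, 0), c(0, 3))), hm), 6)
  hm1 <- flat_map(0, 16, ps = 1)
  expect_equal(path_length(trace_path(rbind(c(0, 0), c(3, 4))), hm1), 5)
  p <- trace_path(rbind(c(0, 0), c(2, 3), c(5, 5), c(9, 2)))
  parts <- sum(
    path_length(trace_path(rbind(c(0, 0), c(2, 3))), hm1),
    path_length(trace_path(rbind(c(2, 3), c(5, 5))), hm1),
    path_length(trace_path(rbind(c(5, 5), c(9, 2))), hm1))
  expect_equal(path_length(p, hm1), parts)
  expect_error(trace_path(rbind(c(0, 0), c(0, 0))), "duplicate")
  expect_error(trace_path(matrix(1, 1, 2)), "2 points")
})

test_that("height profiles interpolate bilinearly and summarize mean/STD", {
  hp <- height_profile(flat_map(1, 16), trace_path(rbind(c(2, 2), c(12, 9))))
  expect_true(all(abs(hp$profile$height_nm - 1) < 1e-12))
  expect_equal(hp$std_height_nm, 0)

  # linear ramp: bilinear interpolation is exact
  rr <- matrix(0:15, 16, 16); cc <- t(rr)
  ramp <- height_map(0.3 * rr + 0.7 * cc, 1)
  path <- trace_path(rbind(c(1, 2), c(13, 11)))
  hp2 <- height_profile(ramp, path)
  rs <- seq(0, 1, length.out = nrow(hp2$profile))
  # positions along the segment
  pos_r <- 1 + rs * 12; pos_c <- 2 + rs * 9
  # profile sampled at uniform arc steps: compare against the analytic plane
  d <- sqrt(12^2 + 9^2)
  arc <- hp2$profile$arc_position_nm
  pr <- 1 + arc / d * 12; pc <- 2 + arc / d * 9
  expect_equal(hp2$profile$height_nm, 0.3 * pr + 0.7 * pc, tolerance = 1e-9)

  # apex of a ridge is the profile maximum at the crossing point
  g <- make_filament(c(32, 64), "line", length_px = 30, sigma_px = 2,
                     amplitude_nm = 2, pixel_size_nm = 1)
  cross <- trace_path(rbind(c(4, 31.5), c(27, 31.5)))
  hp3 <- height_profile(g$map, cross)
  expect_equal(hp3$profile$arc_position_nm[which.max(hp3$profile$height_nm)],
               15.5 - 4, tolerance = 1)
  expect_error(height_profile(ramp, trace_path(rbind(c(0, 0), c(20, 20)))),
               "grid")
})

test_that("width profile recovers the FWHM of a Gaussian ridge", {
  g <- make_filament(c(64, 140), "line", length_px = 100, sigma_px = 2,
                     amplitude_nm = 2, pixel_size_nm = 1)
  tp <- trace_path(cbind(c(31.5, 31.5), c(25, 102)))
  wp <- width_profile(g$map, tp, half_width_px = 8)
  expect_equal(wp$mean_fwhm_nm, 2 * sqrt(2 * log(2)) * 2, tolerance = 0.02)

  # independent oracle: half-max crossing of the analytic cross-section
  # h(s) = A exp(-s^2 / (2 sigma^2)) crosses A/2 at s = sigma sqrt(2 ln 2)
  expect_equal(2 * sqrt(2 * log(2)) * 2, 4.7096, tolerance = 1e-4)

  # halving the pixel size halves the FWHM in nm
  g2 <- make_filament(c(64, 140), "line", length_px = 100, sigma_px = 2,
                      amplitude_nm = 2, pixel_size_nm = 0.5)
  wp2 <- width_profile(g2$map, tp, half_width_px = 8)
  expect_equal(wp2$mean_fwhm_nm, wp$mean_fwhm_nm / 2, tolerance = 0.02)

  # the FWHM/sigma ratio of every converged fit is exactly 2 sqrt(2 ln 2)
  ok <- wp$sections$converged
  ratio <- wp$sections$fwhm_nm[ok] /
    (wp$sections$sigma_px[ok] * g$map$pixel_size_x)
  expect_true(all(abs(ratio - 2 * sqrt(2 * log(2))) < 1e-9))
  expect_equal(round(mean(ratio), 1), 2.4)  # the often-quoted ~2.3-2.4 factor
  expect_error(width_profile(g$map, tp, half_width_px = 2), "at least 3")
})

test_that("skeletons of thin structures keep their chain length", {
  m <- matrix(FALSE, 12, 60); m[6, 6:55] <- TRUE
  hm <- height_map(matrix(as.numeric(m), 12, 60), 1)
  sk <- skeletonize_molecule(hm, 0.5, 5)
  expect_equal(sk$length_nm, 49)
  expect_identical(sum(sk$skeleton), 50L)

  # min-pixel filter discards small components
  m2 <- matrix(0, 40, 80)
  m2[10:11, 5:6] <- 1                      # 4 px speck
  m2[25:27, 10:70] <- 1                    # large ribbon
  sk2 <- skeletonize_molecule(height_map(m2, 1), 0.5, 10)
  expect_false(any(sk2$skeleton[10:11, 5:6]))
  expect_error(skeletonize_molecule(height_map(m2, 1), 2, 10), "no pixels")
  expect_error(skeletonize_molecule(height_map(m2, 1), 0.5, 10000),
               "at least")
})

test_that("semicircular filament skeleton length matches the arc length", {
  f <- make_filament(c(256, 256), "arc", radius_px = 100, angle_rad = pi,
                     sigma_px = 2, amplitude_nm = 2, pixel_size_nm = 1)
  sk <- skeletonize_molecule(f$map, 0.5, 10)
  expect_equal(sk$length_nm, pi * 100, tolerance = 0.05)
})

test_that("skeleton length equals brute-force pair enumeration", {
  # straight and diagonal chains: exact printed values
  m <- matrix(FALSE, 12, 12); m[4, 2:11] <- TRUE
  expect_equal(skeleton_length(m, 1), 9)
  d <- matrix(FALSE, 12, 12); for (i in 2:11) d[i, i] <- TRUE
  expect_equal(skeleton_length(d, 1), 9 * sqrt(2))

  # T-shaped skeleton sums both strokes
  tshape <- matrix(FALSE, 15, 15)
  tshape[3, 3:13] <- TRUE; tshape[4:13, 8] <- TRUE
  expect_equal(skeleton_length(tshape, 1), brute_chain_length(tshape))

  # random thin curves against the oracle, with anisotropic pixels
  set.seed(21)
  for (k in 1:25) {
    mm <- matrix(FALSE, 14, 14)
    r <- 7; c <- 7; mm[r, c] <- TRUE
    for (s in 1:12) {
      st <- sample(c(-1, 0, 1), 2, replace = TRUE)
      r <- min(max(r + st[1], 1), 14); c <- min(max(c + st[2], 1), 14)
      mm[r, c] <- TRUE
    }
    expect_equal(skeleton_length(mm, 1.5, 2.5),
                 brute_chain_length(mm, 1.5, 2.5), tolerance = 1e-12)
  }
  expect_warning(z <- skeleton_length(matrix(FALSE, 4, 4), 1), "empty")
  expect_equal(z, 0)
})

test_that("angles are measured in physical coordinates within [0, 180]", {
  expect_equal(measure_angle(c(0, 0), c(0, 5), c(0, 9))$angle_deg, 180)
  expect_equal(measure_angle(c(0, 5), c(0, 0), c(5, 0))$angle_deg, 90)
  expect_equal(measure_angle(c(1, 0), c(0, 0), c(1, 1))$angle_deg, 45)
  # anisotropic pixels change the physical angle
  a <- measure_angle(c(1, 0), c(0, 0), c(0, 1),
                     pixel_size_x = 2, pixel_size_y = 1)
  expect_equal(a$angle_deg, 90)
  b <- measure_angle(c(1, 0), c(0, 0), c(1, 1),
                     pixel_size_x = 3, pixel_size_y = 1)
  expect_equal(b$angle_deg, atan2(3, 1) * 180 / pi, tolerance = 1e-9)
  expect_error(measure_angle(c(0, 0), c(0, 0), c(1, 1)), "degenerate")
})

test_that("display upsampling is 10x bicubic and reproduces simple fields", {
  hm <- flat_map(2.5, 8)
  up <- upsample_for_display(hm)
  expect_identical(dim(up$heights), c(80L, 80L))
  expect_equal(up$pixel_size_x, hm$pixel_size_x / 10)
  expect_true(all(abs(up$heights - 2.5) < 1e-12))

  rr <- matrix(0:7, 8, 8); cc <- t(rr)
  ramp <- height_map(0.4 * rr - 0.2 * cc, 1)
  up2 <- upsample_for_display(ramp)
  rr10 <- matrix((0:79 + 0.5) / 10 - 0.5, 80, 80); cc10 <- t(rr10)
  expect_equal(up2$heights, 0.4 * rr10 - 0.2 * cc10, tolerance = 1e-9)
})
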
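# Synthetic ground-truth SFM images. Gaussian blobs emulate globular
# protein complexes (a Gaussian of amplitude A and width sigma has
# analytic volume 2*pi*sigma^2*A*pixel_area); Gaussian-profile ridges
# along smooth centerlines emulate DNA and nucleoprotein filaments,
# with the cross-section sigma playing the role of the probe-radius
# broadening (tip-sample convolution). Plane tilt and seeded Gaussian
# noise emulate residual background slope and instrument noise.

#' Synthetic Gaussian blob image with ground truth
#'
#' `h(r) = A * exp(-|r - c|^2 / (2 sigma^2))` on a flat zero background.
#' The ground truth records the analytic volume
#' `2 * pi * sigma^2 * A * pixel_area`. The blob support (4 sigma) must
#' stay clear of the borders, where detection would suppress it.
#'
#' @param shape `c(n_rows, n_cols)`.
#' @param center `(row, col)` blob centre, 0-based, sub-pixel allowed.
#' @param sigma_px Gaussian width, pixels (>= 1).
#' @param amplitude_nm apex height, nm.
#' @param pixel_size_nm lateral calibration, nm/px.
#' @return list with `map` (a [height_map()]) and `truth` (kind,
#'   sigma_px, amplitude_nm, analytic_volume_nm3, center).
#' @export
make_blob <- function(shape, center = (shape - 1) / 2, sigma_px = 3,
                      amplitude_nm = 2, pixel_size_nm = 1) {
  if (sigma_px < 1) stop("sigma_px must be >= 1 pixel")
  if (center[1] < 4 * sigma_px || center[2] < 4 * sigma_px ||
      center[1] > shape[1] - 1 - 4 * sigma_px ||
      center[2] > shape[2] - 1 - 4 * sigma_px)
    stop("blob support (4 sigma) touches the image border; ",
         "border-connected particles are suppressed by detection")
  r <- matrix(0:(shape[1] - 1), shape[1], shape[2])
  cc <- matrix(0:(shape[2] - 1), shape[1], shape[2], byrow = TRUE)
  d2 <- (r - center[1])^2 + (cc - center[2])^2
  h <- amplitude_nm * exp(-d2 / (2 * sigma_px^2))
  map <- height_map(h, pixel_size_nm, pixel_size_nm,
                    source_format = "synthetic", source_path = "<blob>")
  truth <- list(kind = "blob", sigma_px = sigma_px,
                amplitude_nm = amplitude_nm,
                analytic_volume_nm3 = 2 * pi * sigma_px^2 * amplitude_nm *
                  pixel_size_nm^2,
                center = center)
  list(map = map, truth = truth)
}

# densify a polyline to sub-pixel resolution so the distance transform
# below is effectively a distance to the continuous curve
densify_polyline <- function(pts, max_step = 0.25) {
  out <- list()
  for (i in seq_len(nrow(pts) - 1L)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(len / max_step))
    t <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  rbind(do.call(rbind, out), pts[nrow(pts), , drop = FALSE])
}

polyline_length_px <- function(pts) {
  d <- diff(pts)
  sum(sqrt(rowSums(d^2)))
}

# smooth random-walk centerline: cumulative heading with small seeded
# turns, regenerated with the next seed if it self-intersects or leaves
# the allowed margin
random_walk_centerline <- function(shape, margin, length_px, seed,
                                   step_px = 4, max_turn = 0.25,
                                   min_separation_px = 8) {
  for (attempt in 0:49) {
    set.seed(seed + attempt)
    n <- ceiling(length_px / step_px)
    start <- c(stats::runif(1, margin, shape[1] - 1 - margin),
               stats::runif(1, margin, shape[2] - 1 - margin))
    heading <- stats::runif(1, 0, 2 * pi)
    pts <- matrix(NA_real_, n + 1L, 2L)
    pts[1, ] <- start
    ok <- TRUE
    in_bounds <- function(p)
      p[1] >= margin && p[1] <= shape[1] - 1 - margin &&
      p[2] >= margin && p[2] <= shape[2] - 1 - margin
    for (i in seq_len(n)) {
      heading <- heading + stats::runif(1, -max_turn, max_turn)
      nxt <- pts[i, ] + step_px * c(cos(heading), sin(heading))
      if (!in_bounds(nxt)) {
        # steer back toward the centre (with a little jitter) instead
        # of leaving the margin; a turn this sharp breaks smoothness,
        # so the attempt fails if even that step leaves the frame
        ctr <- (shape - 1) / 2
        heading <- atan2(ctr[2] - pts[i, 2], ctr[1] - pts[i, 1])
        heading <- heading + stats::runif(1, -0.2, 0.2)
        nxt <- pts[i, ] + step_px * c(cos(heading), sin(heading))
        if (!in_bounds(nxt)) { ok <- FALSE; break }
      }
      pts[i + 1L, ] <- nxt
      # self-proximity guard: vertices beyond the trailing arc of the
      # walk must stay at least min_separation_px away, so the rendered
      # ridge never approaches (let alone crosses) itself
      skip <- ceiling(min_separation_px / step_px) + 1L
      if (i > skip + 1L) {
        k <- i - skip
        d2 <- rowSums((pts[1:k, , drop = FALSE] -
                       matrix(nxt, k, 2L, byrow = TRUE))^2)
        if (min(d2) < min_separation_px^2) { ok <- FALSE; break }
      }
    }
    if (ok) return(pts)
    message("centerline attempt with seed ", seed + attempt,
            " self-intersected or left the margin; advancing seed")
  }
  stop("could not generate a non-self-intersecting centerline")
}

#' Synthetic filament image with known contour length
#'
#' Renders a smooth ridge `h(p) = A * exp(-d(p, centerline)^2 /
#' (2 sigma^2))` where `d` is the Euclidean distance to the centerline
#' polyline. The ground truth stores the exact polyline length. Three
#' centerline families: a straight `line`, an `arc` (circular segment),
#' or a seeded smooth random `walk`.
#'
#' @param shape `c(n_rows, n_cols)` pixels.
#' @param kind `"line"`, `"arc"` or `"walk"`.
#' @param length_px target centerline length, pixels (for `line`/`walk`).
#' @param radius_px,angle_rad arc radius and subtended angle (for `arc`).
#' @param sigma_px cross-section Gaussian width, px (probe broadening).
#' @param amplitude_nm ridge apex height, nm.
#' @param pixel_size_nm lateral calibration, nm/px.
#' @param seed integer seed for the random walk.
#' @param min_separation_px minimum distance the random walk keeps from
#'   its own earlier course (defaults to 8 sigma so neighbouring passes
#'   of the ridge never overlap).
#' @return list with `map` ([height_map()]) and `truth` (kind,
#'   contour_length_nm, sigma_px, amplitude_nm, centerline, seed).
#' @export
make_filament <- function(shape, kind = c("line", "arc", "walk"),
                          length_px = 100, radius_px = 60,
                          angle_rad = pi, sigma_px = 2, amplitude_nm = 2,
                          pixel_size_nm = 1, seed = 1L,
                          min_separation_px = 8 * sigma_px) {
  kind <- match.arg(kind)
  margin <- 4 * sigma_px + 2
  ctr <- (shape - 1) / 2
  pts <- switch(kind,
    line = {
      half <- length_px / 2
      if (ctr[2] - half < margin || ctr[2] + half > shape[2] - 1 - margin ||
          ctr[1] < margin || ctr[1] > shape[1] - 1 - margin)
        stop("line filament does not fit the image")
      cbind(c(ctr[1], ctr[1]), c(ctr[2] - half, ctr[2] + half))
    },
    arc = {
      if (radius_px < 5 * sigma_px)
        stop("curvature radius must be at least 5 sigma")
      th <- seq(-angle_rad / 2, angle_rad / 2, length.out = 361)
      p <- cbind(ctr[1] + radius_px * cos(th) - radius_px / 2,
                 ctr[2] + radius_px * sin(th))
      if (any(p[, 1] < margin | p[, 1] > shape[1] - 1 - margin |
              p[, 2] < margin | p[, 2] > shape[2] - 1 - margin))
        stop("arc filament does not fit the image")
      p
    },
    walk = random_walk_centerline(shape, margin, length_px, seed,
                                  min_separation_px = min_separation_px))
  dense <- densify_polyline(pts, 0.25)
  h <- render_ridge(shape, dense, sigma_px, amplitude_nm)
  map <- height_map(h, pixel_size_nm, pixel_size_nm,
                    source_format = "synthetic",
                    source_path = paste0("<filament:", kind, ">"))
  truth <- list(kind = "filament", centerline_kind = kind,
                contour_length_px = polyline_length_px(pts),
                contour_length_nm = polyline_length_px(pts) * pixel_size_nm,
                sigma_px = sigma_px, amplitude_nm = amplitude_nm,
                centerline = pts, seed = seed)
  list(map = map, truth = truth)
}

# distance-to-polyline ridge rendering; exact segment distances
# evaluated only inside a 5-sigma band around each segment for speed
render_ridge <- function(shape, dense, sigma_px, amplitude_nm) {
  nr <- shape[1]; nc <- shape[2]
  d2min <- matrix(Inf, nr, nc)
  band <- ceiling(5 * sigma_px)
  for (i in seq_len(nrow(dense) - 1L)) {
    a <- dense[i, ]; b <- dense[i + 1L, ]
    r0 <- max(1L, floor(min(a[1], b[1])) - band + 1L)
    r1 <- min(nr, ceiling(max(a[1], b[1])) + band + 1L)
    c0 <- max(1L, floor(min(a[2], b[2])) - band + 1L)
    c1 <- min(nc, ceiling(max(a[2], b[2])) + band + 1L)
    rows <- (r0:r1) - 1L; cols <- (c0:c1) - 1L
    rg <- matrix(rows, length(rows), length(cols))
    cg <- matrix(cols, length(rows), length(cols), byrow = TRUE)
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((rg - a[1]) * ab[1] + (cg - a[2]) * ab[2]) / max(len2, 1e-12)
    t <- pmin(pmax(t, 0), 1)
    d2 <- (rg - (a[1] + t * ab[1]))^2 + (cg - (a[2] + t * ab[2]))^2
    block <- d2min[r0:r1, c0:c1]
    d2min[r0:r1, c0:c1] <- pmin(block, d2)
  }
  amplitude_nm * exp(-d2min / (2 * sigma_px^2))
}

#' Add a deterministic background tilt
#'
#' Adds `slope_row * row + slope_col * col` (nm, with 0-based indices)
#' to every pixel, emulating residual background slope that upstream
#' flattening would normally remove.
#'
#' @param map a [height_map()].
#' @param slope_row_nm_per_px,slope_col_nm_per_px tilt per pixel.
#' @return a `height_map`.
#' @export
add_plane <- function(map, slope_row_nm_per_px = 0, slope_col_nm_per_px = 0) {
  assert_height_map(map)
  nr <- nrow(map$heights); nc <- ncol(map$heights)
  tilt <- outer(0:(nr - 1), 0:(nc - 1),
                function(r, c) slope_row_nm_per_px * r + slope_col_nm_per_px * c)
  out <- map
  out$heights <- map$heights + tilt
  out
}

#' Add seeded Gaussian height noise
#'
#' @param map a [height_map()].
#' @param sigma_nm noise standard deviation, nm.
#' @param seed integer seed (deterministic regeneration).
#' @return a `height_map`.
#' @export
add_noise <- function(map, sigma_nm, seed = 1L) {
  assert_height_map(map)
  if (sigma_nm < 0) stop("sigma_nm must be non-negative")
  out <- map
  if (sigma_nm > 0) {
    set.seed(seed)
    out$heights <- map$heights +
      matrix(stats::rnorm(length(map$heights), 0, sigma_nm),
             nrow(map$heights), ncol(map$heights))
  }
  out
}
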
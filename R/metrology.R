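#' Freehand trace path
#'
#' An ordered polyline in 0-based sub-pixel `(row, col)` coordinates,
#' as produced by freehand tracing over a displayed image (or supplied
#' from a CSV file in the CLI). Consecutive duplicate points are
#' rejected.
#'
#' @param points two-column numeric matrix (row, col), at least 2 points.
#' @param closed whether the path closes back on its first point.
#' @return an object of class `trace_path`.
#' @export
trace_path <- function(points, closed = FALSE) {
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 2L)
    stop("a trace path needs a two-column (row, col) matrix with >= 2 points")
  if (!all(is.finite(points))) stop("trace path contains non-finite points")
  d <- diff(points)
  if (any(rowSums(abs(d)) == 0))
    stop("trace path contains consecutive duplicate points")
  pts <- unname(points)
  if (closed) pts <- rbind(pts, pts[1, ])
  structure(list(points = pts, closed = isTRUE(closed)),
            class = "trace_path")
}

#' @export
print.trace_path <- function(x, ...) {
  cat(sprintf("<trace_path> %d points%s\n", nrow(x$points),
              if (x$closed) " (closed)" else ""))
  invisible(x)
}

#' Physical length of a traced path
#'
#' Sum of Euclidean segment lengths with the per-axis pixel sizes
#' applied: `sqrt((drow * pixel_size_y)^2 + (dcol * pixel_size_x)^2)`.
#'
#' @param path a [trace_path()].
#' @param map the [height_map()] providing the pixel calibration.
#' @return length in nm.
#' @export
path_length <- function(path, map) {
  stopifnot(inherits(path, "trace_path"))
  assert_height_map(map)
  d <- diff(path$points)
  sum(sqrt((d[, 1] * map$pixel_size_y)^2 + (d[, 2] * map$pixel_size_x)^2))
}

# Resample a polyline at uniform arc steps (in pixel units), returning
# sub-pixel (row, col) sample positions and their arc positions in nm.
resample_path <- function(path, map, step_px = 1) {
  pts <- path$points
  d <- diff(pts)
  seg_px <- sqrt(d[, 1]^2 + d[, 2]^2)
  seg_nm <- sqrt((d[, 1] * map$pixel_size_y)^2 + (d[, 2] * map$pixel_size_x)^2)
  cum_px <- c(0, cumsum(seg_px))
  cum_nm <- c(0, cumsum(seg_nm))
  total_px <- cum_px[length(cum_px)]
  s <- seq(0, total_px, by = step_px)
  if (s[length(s)] < total_px) s <- c(s, total_px)
  seg_idx <- pmin(findInterval(s, cum_px, rightmost.closed = TRUE),
                  nrow(pts) - 1L)
  frac <- (s - cum_px[seg_idx]) / pmax(seg_px[seg_idx], .Machine$double.eps)
  pos <- pts[seg_idx, , drop = FALSE] + d[seg_idx, , drop = FALSE] * frac
  arc_nm <- cum_nm[seg_idx] + seg_nm[seg_idx] * frac
  list(pos = pos, arc_nm = arc_nm)
}

#' Height profile along a traced path
#'
#' Resamples the path at uniform arc steps and reads the height at each
#' sample by bilinear interpolation of the unmodified image. The summary
#' reports the mean and standard deviation of the sampled heights, the
#' quantities shown above the profile plot in interactive use.
#'
#' @param map a [height_map()].
#' @param path a [trace_path()] lying inside the image.
#' @param step_px resampling step along the path, pixels of arc.
#' @return a `height_profile` object: data frame `profile` with columns
#'   `arc_position_nm`, `height_nm`, plus `mean_height_nm` and
#'   `std_height_nm`.
#' @export
height_profile <- function(map, path, step_px = 1) {
  assert_height_map(map)
  stopifnot(inherits(path, "trace_path"))
  rs <- resample_path(path, map, step_px)
  hts <- bilinear(map$heights, rs$pos[, 1], rs$pos[, 2])
  structure(list(profile = data.frame(arc_position_nm = rs$arc_nm,
                                      height_nm = hts),
                 mean_height_nm = mean(hts),
                 std_height_nm = stats::sd(hts)),
            class = "height_profile")
}

#' @export
print.height_profile <- function(x, ...) {
  cat(sprintf("<height_profile> %d samples over %.4g nm; mean %.4g +/- %.4g nm\n",
              nrow(x$profile), max(x$profile$arc_position_nm),
              x$mean_height_nm, x$std_height_nm))
  invisible(x)
}

# Fit h(s) = A exp(-(s-c)^2 / (2 sigma^2)) + b to one cross-section.
# Initial values: A = max-min, c = argmax, sigma = half width at half
# max of the raw samples, b = min. The fit is declared failed if the
# optimizer does not converge, sigma exceeds the window length, or the
# amplitude is not above 2x the residual RMS.
fit_gaussian_section <- function(s, h) {
  init_b <- min(h)
  init_a <- max(h) - init_b
  if (init_a <= 0) return(NULL)
  imax <- which.max(h)
  init_c <- s[imax]
  half <- init_b + init_a / 2
  above <- which(h >= half)
  init_sigma <- max((s[max(above)] - s[min(above)]) / 2.3548, diff(range(s)) / 50)
  residual_fn <- function(p)
    p[1] * exp(-(s - p[2])^2 / (2 * p[3]^2)) + p[4] - h
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(init_a, init_c, init_sigma, init_b),
                       fn = residual_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4)) return(NULL)
  p <- fit$par
  sigma <- abs(p[3])
  amp <- p[1]
  rms <- sqrt(mean(residual_fn(p)^2))
  window <- diff(range(s))
  if (!is.finite(sigma) || sigma <= 0 || sigma > window) return(NULL)
  if (!(amp > 2 * rms)) return(NULL)
  list(amplitude = amp, center = p[2], sigma = sigma, baseline = p[4])
}

#' Width (FWHM) profile along a traced path
#'
#' At each resampled path point a cross-section orthogonal to the local
#' path tangent (central difference) is sampled by bicubic (Keys)
#' interpolation at 0.25 px steps over a total length of
#' `2 * half_width_px`. Each cross-section is fitted with a Gaussian
#' plus baseline; the full width at half maximum is
#' `2 * sqrt(2 * ln 2) ~ 2.355` times the fitted standard deviation,
#' converted to nm with the pixel size along the cross-section
#' direction. Cross-sections whose fit fails to converge (or is
#' degenerate) are flagged and excluded from the mean/STD summary.
#' Cross-sections whose window leaves the image are skipped.
#'
#' @param map a [height_map()].
#' @param path a [trace_path()].
#' @param half_width_px half-length of the orthogonal window, >= 3 px.
#' @param step_px resampling step along the path, px of arc.
#' @return a `width_profile` object: data frame `sections` (columns
#'   `arc_position_nm`, `amplitude_nm`, `center_px`, `sigma_px`,
#'   `fwhm_nm`, `max_height_nm`, `converged`), `mean_fwhm_nm`,
#'   `std_fwhm_nm`, `n_converged`.
#' @export
width_profile <- function(map, path, half_width_px = 5, step_px = 1) {
  assert_height_map(map)
  stopifnot(inherits(path, "trace_path"))
  if (half_width_px < 3) stop("half_width_px must be at least 3 pixels")
  rs <- resample_path(path, map, step_px)
  n <- nrow(rs$pos)
  # central-difference tangents, one-sided at the ends
  tang <- matrix(0, n, 2)
  if (n >= 3) tang[2:(n - 1), ] <- rs$pos[3:n, ] - rs$pos[1:(n - 2), ]
  tang[1, ] <- rs$pos[2, ] - rs$pos[1, ]
  tang[n, ] <- rs$pos[n, ] - rs$pos[n - 1, ]
  tlen <- sqrt(rowSums(tang^2))
  tang <- tang / pmax(tlen, .Machine$double.eps)
  normal <- cbind(-tang[, 2], tang[, 1])     # rotate 90 degrees

  svals <- seq(-half_width_px, half_width_px, by = 0.25)
  nr <- nrow(map$heights); nc <- ncol(map$heights)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pr <- rs$pos[i, 1] + svals * normal[i, 1]
    pc <- rs$pos[i, 2] + svals * normal[i, 2]
    if (any(pr < 0 | pr > nr - 1 | pc < 0 | pc > nc - 1)) next
    hs <- bicubic(map$heights, pr, pc)
    # physical pixel size along the cross-section direction
    ps_dir <- sqrt((normal[i, 1] * map$pixel_size_y)^2 +
                   (normal[i, 2] * map$pixel_size_x)^2)
    fit <- fit_gaussian_section(svals, hs)
    if (is.null(fit)) {
      rows[[i]] <- data.frame(arc_position_nm = rs$arc_nm[i],
                              amplitude_nm = NA_real_, center_px = NA_real_,
                              sigma_px = NA_real_, fwhm_nm = NA_real_,
                              max_height_nm = max(hs), converged = FALSE)
    } else {
      rows[[i]] <- data.frame(arc_position_nm = rs$arc_nm[i],
                              amplitude_nm = fit$amplitude,
                              center_px = fit$center,
                              sigma_px = fit$sigma,
                              fwhm_nm = 2 * sqrt(2 * log(2)) * fit$sigma * ps_dir,
                              max_height_nm = max(hs),
                              converged = TRUE)
    }
  }
  sections <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(sections) || !any(sections$converged))
    stop("no cross-section Gaussian fit converged; cannot estimate width")
  ok <- sections$converged
  structure(list(sections = sections,
                 mean_fwhm_nm = mean(sections$fwhm_nm[ok]),
                 std_fwhm_nm = stats::sd(sections$fwhm_nm[ok]),
                 n_converged = sum(ok)),
            class = "width_profile")
}

#' @export
print.width_profile <- function(x, ...) {
  cat(sprintf("<width_profile> %d/%d converged cross-sections; FWHM %.4g +/- %.4g nm\n",
              x$n_converged, nrow(x$sections), x$mean_fwhm_nm, x$std_fwhm_nm))
  invisible(x)
}

#' Background-subtracted volume of a selected particle
#'
#' `volume = sum over particle pixels of (height - background) *
#' pixel_size_x * pixel_size_y`, evaluated on the unmodified heights.
#'
#' @param map a [height_map()].
#' @param labeled a `labeled_particles` object.
#' @param selected label id to measure; defaults to the largest particle.
#' @param background background height, nm (see [estimate_background()]).
#' @return a `volume_result`: `volume_nm3`, `background_nm`, `n_pixels`.
#' @export
particle_volume <- function(map, labeled, selected = labeled$selected,
                            background = 0) {
  assert_height_map(map)
  stopifnot(inherits(labeled, "labeled_particles"))
  if (!selected %in% seq_len(labeled$n_particles))
    stop("no particle with label ", selected)
  px <- labeled$labels == selected
  vol <- sum(map$heights[px] - background) *
    map$pixel_size_x * map$pixel_size_y
  structure(list(volume_nm3 = vol, background_nm = background,
                 n_pixels = sum(px)),
            class = "volume_result")
}

#' @export
print.volume_result <- function(x, ...) {
  cat(sprintf("<volume_result> %.6g nm^3 over %d px (background %.4g nm)\n",
              x$volume_nm3, x$n_pixels, x$background_nm))
  invisible(x)
}

#' Skeletonize a molecule and measure its contour length
#'
#' Thresholds the heights, discards connected components smaller than
#' `min_pixels`, thins the remaining support to a one-pixel-wide medial
#' curve without breaking it apart, and sums the 8-connected chain
#' length (1 or sqrt(2) pixel steps, scaled to nm).
#'
#' @param map a [height_map()].
#' @param height_threshold_nm pixels at or above this height form the
#'   support; must be below the image maximum.
#' @param min_pixels components with fewer support pixels are ignored.
#' @return a `skeleton_result`: `skeleton` (logical matrix),
#'   `length_nm`, `height_threshold_nm`, `min_pixels`.
#' @export
skeletonize_molecule <- function(map, height_threshold_nm, min_pixels = 10L) {
  assert_height_map(map)
  support <- map$heights >= height_threshold_nm
  if (!any(support))
    stop("height threshold ", height_threshold_nm,
         " nm leaves no pixels; skeleton is empty")
  lab <- label_components8(support)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_pixels)
  if (length(keep) == 0L)
    stop("no component has at least ", min_pixels, " pixels")
  support <- lab %in% keep
  dim(support) <- dim(map$heights)
  skel <- thin_zhang_suen(support)
  structure(list(skeleton = skel,
                 length_nm = skeleton_length(skel, map$pixel_size_x,
                                             map$pixel_size_y),
                 height_threshold_nm = height_threshold_nm,
                 min_pixels = as.integer(min_pixels)),
            class = "skeleton_result")
}

#' @export
print.skeleton_result <- function(x, ...) {
  cat(sprintf("<skeleton_result> %d skeleton px, length %.6g nm (threshold %.4g nm, min %d px)\n",
              sum(x$skeleton), x$length_nm, x$height_threshold_nm,
              x$min_pixels))
  invisible(x)
}

#' Chain length of a one-pixel-wide skeleton
#'
#' Sums the physical distance over every 8-adjacent pair of skeleton
#' pixels, each pair counted once: lateral neighbours contribute one
#' pixel size, diagonal neighbours `sqrt(psx^2 + psy^2)`. Branched
#' skeletons sum all branches. An empty skeleton yields 0 with a
#' warning.
#'
#' @param skeleton logical matrix.
#' @param pixel_size_x,pixel_size_y nm/px.
#' @return length in nm.
#' @export
skeleton_length <- function(skeleton, pixel_size_x, pixel_size_y = pixel_size_x) {
  stopifnot(is.matrix(skeleton), is.logical(skeleton))
  if (!any(skeleton)) {
    warning("empty skeleton; length is 0")
    return(0)
  }
  nr <- nrow(skeleton); nc <- ncol(skeleton)
  total <- 0
  pair_count <- function(dr, dc) {
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    sum(skeleton[r1, c1, drop = FALSE] &
        skeleton[r1 + dr, c1 + dc, drop = FALSE])
  }
  diag_nm <- sqrt(pixel_size_x^2 + pixel_size_y^2)
  total <- total + pair_count(0L, 1L) * pixel_size_x
  total <- total + pair_count(1L, 0L) * pixel_size_y
  total <- total + pair_count(1L, 1L) * diag_nm
  total <- total + pair_count(-1L, 1L) * diag_nm
  total
}

#' Angle between two segments meeting at a vertex
#'
#' Computes the angle at `vertex` between the segments to `p1` and `p2`,
#' in physical (nm) coordinates so anisotropic pixels are handled, as
#' the arccosine of the normalized dot product. Result in degrees,
#' between 0 and 180.
#'
#' @param p1,vertex,p2 length-2 numeric vectors, (row, col) pixel
#'   coordinates (sub-pixel allowed).
#' @param pixel_size_x,pixel_size_y nm/px used to convert to physical
#'   coordinates.
#' @return an `angle_measurement` with element `angle_deg`.
#' @export
measure_angle <- function(p1, vertex, p2, pixel_size_x = 1,
                          pixel_size_y = pixel_size_x) {
  to_nm <- function(p) c(p[1] * pixel_size_y, p[2] * pixel_size_x)
  v1 <- to_nm(p1) - to_nm(vertex)
  v2 <- to_nm(p2) - to_nm(vertex)
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0)
    stop("degenerate angle: a point coincides with the vertex")
  cosang <- sum(v1 * v2) / (n1 * n2)
  cosang <- min(1, max(-1, cosang))
  structure(list(p1 = p1, vertex = vertex, p2 = p2,
                 angle_deg = acos(cosang) * 180 / pi),
            class = "angle_measurement")
}

#' @export
print.angle_measurement <- function(x, ...) {
  cat(sprintf("<angle_measurement> %.2f degrees\n", x$angle_deg))
  invisible(x)
}

#' Upsample a height map for display
#'
#' Increases the resolution by `factor` (default 10) using cubic
#' convolution over the 4x4 nearest-neighbour pixels (separable Keys
#' kernel, a = -0.5, which reproduces constant and linear fields
#' exactly; borders are padded by linear extrapolation). Pixel sizes are
#' divided by the factor. Display-only: measurements always use the
#' original grid.
#'
#' @param map a [height_map()].
#' @param factor integer magnification, default 10.
#' @return a `height_map` with `factor`-times the resolution.
#' @export
upsample_for_display <- function(map, factor = 10L) {
  assert_height_map(map)
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be a positive integer")
  h <- map$heights
  h2 <- apply(h, 2, cubic_upsample_1d, factor = factor)       # rows
  h3 <- t(apply(h2, 1, cubic_upsample_1d, factor = factor))   # cols
  out <- map
  out$heights <- h3
  out$pixel_size_x <- map$pixel_size_x / factor
  out$pixel_size_y <- map$pixel_size_y / factor
  out
}

# 1-D cubic convolution (Keys, a = -0.5) resampling a vector of length n
# to n*factor samples; pads by linear extrapolation so that linear
# ramps are reproduced exactly.
cubic_upsample_1d <- function(v, factor) {
  n <- length(v)
  vp <- c(3 * v[1] - 2 * v[2], 2 * v[1] - v[2], v,
          2 * v[n] - v[n - 1], 3 * v[n] - 2 * v[n - 1])
  xout <- (seq_len(n * factor) - 0.5) / factor - 0.5   # 0-based centres
  i0 <- floor(xout)
  t <- xout - i0
  a <- -0.5
  w0 <- a * t^3 - 2 * a * t^2 + a * t
  w1 <- (a + 2) * t^3 - (a + 3) * t^2 + 1
  w2 <- -(a + 2) * t^3 + (2 * a + 3) * t^2 - a * t
  w3 <- -a * t^3 + a * t^2
  at <- function(i) vp[pmin(pmax(i + 3L, 1L), n + 4L)]  # vp index of x=i
  w0 * at(i0 - 1L) + w1 * at(i0) + w2 * at(i0 + 1L) + w3 * at(i0 + 2L)
}

#' Expected contour length of B-form double-stranded DNA
#'
#' The canonical helical rise of B-form dsDNA is 0.332 nm per base
#' pair, so a molecule of `n_bp` base pairs is expected to span
#' `n_bp * 0.332` nm. Used as the reference against which measured
#' skeleton or freehand contour lengths are compared (e.g. a 2686 bp
#' plasmid corresponds to ~892 nm).
#'
#' @param n_bp number of base pairs.
#' @param rise_nm_per_bp helical rise, nm per base pair.
#' @return expected contour length, nm.
#' @export
bform_contour_nm <- function(n_bp, rise_nm_per_bp = 0.332)
  n_bp * rise_nm_per_bp
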
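#' Sobel gradient magnitude of a height map
#'
#' Convolves the image with the two 3x3 Sobel kernels (horizontal and
#' vertical derivative) and combines them as the square root of the sum
#' of squares, `G = sqrt(Gx^2 + Gy^2)`. Borders are handled by edge
#' replication, so the output has the same shape as the input. Gradient
#' units are nm per pixel (heights differenced over pixel index), which
#' makes the detection threshold behave identically across scan sizes
#' for the same image content.
#'
#' @param map a [height_map()].
#' @return numeric matrix of gradient magnitudes, nm/px.
#' @export
sobel_magnitude <- function(map) {
  assert_height_map(map)
  h <- pad_replicate(map$heights, 1L)
  nr <- nrow(map$heights); nc <- ncol(map$heights)
  sh <- function(dr, dc) h[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  # Sobel x (column derivative) and y (row derivative), correlation form
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  sqrt(gx^2 + gy^2)
}

# Automatic base threshold for Sobel edge maps: 4 x root-mean-square of
# the gradient magnitude. Deterministic and scale-covariant; the user's
# threshold_factor multiplies it.
sobel_base_threshold <- function(grad) 4 * sqrt(mean(grad^2))

#' Detect particles by gradient thresholding
#'
#' The core segmentation pipeline: (1) Sobel gradient magnitude;
#' (2) automatic base threshold (4 x RMS of the gradient) scaled by the
#' user's `threshold_factor`; (3) morphological closing (3x3), hole
#' filling, then opening (3x3); (4) suppression of components connected
#' to the image border (8-connectivity). The resulting binary mask is
#' meant to be applied to the unmodified height data.
#'
#' @param map a [height_map()].
#' @param threshold_factor positive multiplier on the automatic base
#'   threshold; larger is more stringent.
#' @return an object of class `particle_mask` with elements `mask`
#'   (logical matrix), `threshold_factor` and `base_threshold` (nm/px).
#' @export
detect_particles <- function(map, threshold_factor = 1) {
  assert_height_map(map)
  if (!is.numeric(threshold_factor) || length(threshold_factor) != 1L ||
      !is.finite(threshold_factor) || threshold_factor <= 0)
    stop("threshold_factor must be a single positive number")
  grad <- sobel_magnitude(map)
  base <- sobel_base_threshold(grad)
  edge <- grad >= threshold_factor * base
  mask <- clean_mask(edge)
  structure(list(mask = mask,
                 threshold_factor = threshold_factor,
                 base_threshold = base),
            class = "particle_mask")
}

# closing -> hole fill -> opening (3x3 box), then border suppression
clean_mask <- function(edge) {
  if (!any(edge)) return(edge)
  kern <- EBImage::makeBrush(3L, shape = "box")
  m <- matrix(as.numeric(edge), nrow(edge), ncol(edge))
  m <- EBImage::closing(m, kern)
  m <- EBImage::fillHull(m)
  m <- EBImage::opening(m, kern)
  mask <- m > 0.5
  drop_border_components(mask)
}

# remove 8-connected components touching any image border
drop_border_components <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- label_components8(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  border_labels <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  border_labels <- border_labels[border_labels > 0L]
  if (length(border_labels)) mask[lab %in% border_labels] <- FALSE
  mask
}

#' @export
print.particle_mask <- function(x, ...) {
  cat(sprintf("<particle_mask> %d x %d px, %d particle pixels, factor %.3g, base threshold %.4g nm/px\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              x$threshold_factor, x$base_threshold))
  invisible(x)
}

#' Mean background height outside the detected particles
#'
#' Arithmetic mean of the unmodified heights over all pixels where the
#' mask is false.
#'
#' @param map a [height_map()].
#' @param mask a `particle_mask` (or plain logical matrix) aligned with
#'   `map`.
#' @return background height, nm.
#' @export
estimate_background <- function(map, mask) {
  assert_height_map(map)
  m <- as_mask_matrix(mask, dim(map$heights))
  if (all(m))
    stop("mask covers every pixel; no background left to estimate")
  mean(map$heights[!m])
}

as_mask_matrix <- function(mask, dims) {
  m <- if (inherits(mask, "particle_mask")) mask$mask else mask
  if (!is.matrix(m) || !is.logical(m))
    stop("mask must be a particle_mask or a logical matrix")
  if (!identical(dim(m), as.integer(dims)))
    stop("mask shape does not match the height map")
  m
}

#' Label particles and select the largest
#'
#' 8-connected labeling of a particle mask; labels are numbered by first
#' appearance in row-major scan order, and the particle occupying the
#' largest pixel area is selected (ties broken by the smallest label id,
#' i.e. first in scan order).
#'
#' @param mask a `particle_mask` or logical matrix; must contain at
#'   least one true pixel.
#' @return a `labeled_particles` object: `labels` (integer matrix, 0 =
#'   background), `n_particles`, `areas_px`, `selected` (label id of the
#'   largest particle).
#' @export
label_and_select_largest <- function(mask) {
  m <- if (inherits(mask, "particle_mask")) mask$mask else mask
  if (!is.matrix(m) || !is.logical(m))
    stop("mask must be a particle_mask or a logical matrix")
  if (!any(m)) stop("no particles detected: the mask is empty")
  lab <- label_components8(m)
  n <- max(lab)
  areas <- tabulate(lab[lab > 0L], nbins = n)
  structure(list(labels = lab, n_particles = n, areas_px = areas,
                 selected = which.max(areas)),
            class = "labeled_particles")
}

#' @export
print.labeled_particles <- function(x, ...) {
  cat(sprintf("<labeled_particles> %d particle(s), areas [px]: %s; selected = %d\n",
              x$n_particles,
              paste(utils::head(x$areas_px, 10L), collapse = ", "),
              x$selected))
  invisible(x)
}

#' Conventional intensity-threshold mask (comparison baseline)
#'
#' Marks pixels whose height is at least `fraction_of_max` times the
#' image maximum. No morphology is applied; this is the conventional
#' thresholding that gradient-based detection is compared against.
#'
#' @param map a [height_map()].
#' @param fraction_of_max fraction in (0, 1), e.g. 0.10/0.15/0.20.
#' @return a `particle_mask` (with `base_threshold` in nm).
#' @export
intensity_threshold_mask <- function(map, fraction_of_max) {
  assert_height_map(map)
  if (!is.numeric(fraction_of_max) || length(fraction_of_max) != 1L ||
      !is.finite(fraction_of_max) ||
      fraction_of_max <= 0 || fraction_of_max >= 1)
    stop("fraction_of_max must lie strictly between 0 and 1")
  thr <- fraction_of_max * max(map$heights)
  structure(list(mask = map$heights >= thr,
                 threshold_factor = fraction_of_max,
                 base_threshold = thr),
            class = "particle_mask")
}
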
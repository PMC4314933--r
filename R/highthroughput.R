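# High-throughput ("edges") mode: detect every particle in an image or
# folder, compute per-particle region statistics on the unmodified
# heights, histogram the volumes, optionally normalize to molecular
# mass with a known standard.

# region properties of one labeled particle, in physical units.
# Ellipse = same-second-moments ellipse of the pixel-centre set (full
# axis lengths 4*sqrt(eigenvalue)); solidity = pixel count / pixel
# count of the rasterized convex hull.
particle_region_props <- function(rows, cols, psx, psy) {
  y <- rows * psy; x <- cols * psx
  n <- length(rows)
  cy <- mean(y); cx <- mean(x)
  # second central moments with the 1/12 per-pixel variance of a unit
  # square, the standard discrete-to-continuous correction
  myy <- mean((y - cy)^2) + psy^2 / 12
  mxx <- mean((x - cx)^2) + psx^2 / 12
  mxy <- mean((y - cy) * (x - cx))
  tr <- myy + mxx
  det <- myy * mxx - mxy^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 0)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  ecc <- if (l1 <= 0) 0 else sqrt(pmax(0, 1 - l2 / l1))
  solidity <- if (n <= 2) 1 else {
    hull <- grDevices::chull(cols, rows)
    hx <- cols[hull]; hy <- rows[hull]
    n / max(n, count_pixels_in_hull(hx, hy))
  }
  list(solidity = solidity, eccentricity = ecc,
       major_axis_nm = major, minor_axis_nm = minor,
       axis_ratio = if (major > 0) minor / major else 1)
}

# count integer pixel centres inside (or on) the convex hull polygon
count_pixels_in_hull <- function(hx, hy) {
  if (length(hx) < 3L) return(length(hx))
  total <- 0L
  for (r in seq(min(hy), max(hy))) {
    xs <- hull_row_span(hx, hy, r)
    if (!is.null(xs)) total <- total + max(0L, floor(xs[2]) - ceiling(xs[1]) + 1L)
  }
  total
}

# intersection of the hull polygon with the horizontal line y = r
hull_row_span <- function(hx, hy, r) {
  n <- length(hx)
  xs <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    y1 <- hy[i]; y2 <- hy[j]
    if ((y1 <= r && y2 >= r) || (y2 <= r && y1 >= r)) {
      if (y1 == y2) xs <- c(xs, hx[i], hx[j])
      else xs <- c(xs, hx[i] + (r - y1) / (y2 - y1) * (hx[j] - hx[i]))
    }
  }
  if (length(xs) == 0) NULL else range(xs)
}

#' Detect and measure every particle in an image
#'
#' Runs the gradient detection pipeline ([detect_particles()], border
#' suppression included) on the whole image, labels all particles
#' (8-connected) and computes a statistics record per particle on the
#' unmodified heights, using the shared background estimate (image mean
#' excluding all detected particles). Ellipse properties come from the
#' second moments of the particle's pixel distribution, axes in nm;
#' `sum_intensity_nm` is the background-subtracted height sum, so
#' `sum_intensity_nm * pixel_area = volume_nm3`.
#'
#' @param map a [height_map()].
#' @param threshold_factor detection stringency (see
#'   [detect_particles()]).
#' @param image label for the `image` column (defaults to the source
#'   path).
#' @return data frame of particle records with columns `image`, `label`,
#'   `sum_intensity_nm`, `solidity`, `pixel_size_nm`, `axis_ratio`,
#'   `volume_nm3`, `eccentricity`, `minor_axis_nm`, `major_axis_nm`;
#'   zero rows if nothing is detected.
#' @export
detect_all <- function(map, threshold_factor = 1, image = NULL) {
  assert_height_map(map)
  if (is.null(image))
    image <- if (nzchar(map$source_path)) basename(map$source_path) else "<image>"
  empty <- data.frame(image = character(), label = integer(),
                      sum_intensity_nm = numeric(), solidity = numeric(),
                      pixel_size_nm = numeric(), axis_ratio = numeric(),
                      volume_nm3 = numeric(), eccentricity = numeric(),
                      minor_axis_nm = numeric(), major_axis_nm = numeric(),
                      stringsAsFactors = FALSE)
  pm <- detect_particles(map, threshold_factor)
  if (!any(pm$mask)) return(empty)
  background <- estimate_background(map, pm)
  lp <- label_and_select_largest(pm)
  psx <- map$pixel_size_x; psy <- map$pixel_size_y
  recs <- lapply(seq_len(lp$n_particles), function(lb) {
    idx <- which(lp$labels == lb)
    rows <- ((idx - 1L) %% nrow(lp$labels))
    cols <- ((idx - 1L) %/% nrow(lp$labels))
    hsum <- sum(map$heights[idx] - background)
    props <- particle_region_props(rows, cols, psx, psy)
    data.frame(image = image, label = lb,
               sum_intensity_nm = hsum,
               solidity = props$solidity,
               pixel_size_nm = psx,
               axis_ratio = props$axis_ratio,
               volume_nm3 = hsum * psx * psy,
               eccentricity = props$eccentricity,
               minor_axis_nm = props$minor_axis_nm,
               major_axis_nm = props$major_axis_nm,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Batch particle detection over a folder of images
#'
#' Applies the same `threshold_factor` to every readable image in the
#' directory and concatenates the per-particle records, tagged with the
#' file names. Unreadable files are skipped with a warning, not fatal.
#' Mixed-format folders should be run once per format with
#' `format_hint`.
#'
#' @param dir directory containing image files.
#' @param threshold_factor detection stringency shared by all images.
#' @param format_hint optional dialect passed to [load_any()].
#' @param ... reader options (calibration for ascii/raster files).
#' @return data frame of particle records (as [detect_all()]).
#' @export
batch_folder <- function(dir, threshold_factor = 1, format_hint = NULL, ...) {
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  files <- sort(list.files(dir, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files found in ", dir)
  out <- list()
  n_ok <- 0L
  for (f in files) {
    map <- tryCatch(load_any(f, format_hint = format_hint, ...),
                    error = function(e) {
                      warning("skipping unreadable file ", f, ": ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
    if (is.null(map)) next
    n_ok <- n_ok + 1L
    out[[length(out) + 1L]] <- detect_all(map, threshold_factor,
                                          image = basename(f))
  }
  if (n_ok == 0L) stop("no readable images in ", dir)
  do.call(rbind, out)
}

#' Histogram of particle volumes
#'
#' Equal-width bins over `[v_min, v_max]`; records outside the bounds
#' are excluded. Works on raw volumes (nm^3) or, after
#' [calibrate_to_kda()], on masses (pass `value_col = "mass_kda"`).
#'
#' @param records data frame of particle records.
#' @param v_min,v_max inclusion bounds (`v_min < v_max`).
#' @param n_bins number of bins, >= 1.
#' @param value_col column to histogram, default `"volume_nm3"`.
#' @return a `volume_histogram`: `bin_edges`, `counts`, `v_min`,
#'   `v_max`, `n_bins`.
#' @export
volume_histogram <- function(records, v_min, v_max, n_bins = 15L,
                             value_col = "volume_nm3") {
  if (!is.numeric(v_min) || !is.numeric(v_max) || v_min >= v_max)
    stop("need v_min < v_max")
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L) stop("n_bins must be >= 1")
  v <- records[[value_col]]
  if (is.null(v)) stop("records have no column '", value_col, "'")
  v <- v[v >= v_min & v <= v_max]
  edges <- seq(v_min, v_max, length.out = n_bins + 1L)
  idx <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  structure(list(bin_edges = edges,
                 counts = tabulate(idx, nbins = n_bins),
                 v_min = v_min, v_max = v_max, n_bins = n_bins),
            class = "volume_histogram")
}

#' @export
print.volume_histogram <- function(x, ...) {
  cat(sprintf("<volume_histogram> %d bins over [%.4g, %.4g], %d particles in range\n",
              x$n_bins, x$v_min, x$v_max, sum(x$counts)))
  invisible(x)
}

#' Calibrate particle volumes to molecular mass
#'
#' Linear volume-to-mass map through the origin using a standard of
#' known volume and mass (e.g. E. coli RNA polymerase, 450 kDa):
#' `mass_kda = volume_nm3 * standard_mass_kda / standard_volume_nm3`.
#' Tip-sample convolution makes absolute SFM volumes calibration-
#' dependent, hence the explicit standard.
#'
#' @param records data frame with a `volume_nm3` column.
#' @param standard_volume_nm3 measured volume of the standard, > 0.
#' @param standard_mass_kda known mass of the standard, > 0.
#' @return `records` with an added `mass_kda` column.
#' @export
calibrate_to_kda <- function(records, standard_volume_nm3,
                             standard_mass_kda) {
  if (!is.numeric(standard_volume_nm3) || standard_volume_nm3 <= 0)
    stop("standard_volume_nm3 must be positive")
  if (!is.numeric(standard_mass_kda) || standard_mass_kda <= 0)
    stop("standard_mass_kda must be positive")
  records$mass_kda <- records$volume_nm3 * standard_mass_kda /
    standard_volume_nm3
  records
}
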
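#' Calibrated SFM height map
#'
#' The universal in-memory representation every file reader normalizes to:
#' a matrix of surface heights in nanometres plus the lateral pixel
#' calibration in nm/px. Row 1 of the matrix is the top scan line; the
#' public coordinate convention throughout the package is 0-based
#' `(row, col)` with half-open ranges (see [region_selection()]).
#'
#' @param heights numeric matrix of surface heights, nm. Must be finite,
#'   at least 2 x 2.
#' @param pixel_size_x,pixel_size_y lateral calibration, nm per pixel,
#'   along columns (x, fast scan axis) and rows (y). Both must be > 0.
#'   Non-square pixels are carried separately and honoured by every
#'   length/area/volume formula.
#' @param source_format one of `"nanoscope"`, `"jpk"`, `"ibw"`, `"ascii"`,
#'   `"raster"`, or `"synthetic"` for generated images.
#' @param source_path file of origin (informational).
#' @param channel_name optional channel label from the source file.
#' @return an object of class `height_map`.
#' @export
height_map <- function(heights, pixel_size_x, pixel_size_y = pixel_size_x,
                       source_format = "synthetic", source_path = "",
                       channel_name = NULL) {
  if (!is.matrix(heights) || !is.numeric(heights))
    stop("heights must be a numeric matrix")
  if (nrow(heights) < 2L || ncol(heights) < 2L)
    stop("height map must have at least 2 rows and 2 columns")
  if (!all(is.finite(heights)))
    stop("height map contains non-finite values")
  if (!is.numeric(pixel_size_x) || length(pixel_size_x) != 1L ||
      !is.finite(pixel_size_x) || pixel_size_x <= 0)
    stop("pixel_size_x must be a single positive number (nm/px)")
  if (!is.numeric(pixel_size_y) || length(pixel_size_y) != 1L ||
      !is.finite(pixel_size_y) || pixel_size_y <= 0)
    stop("pixel_size_y must be a single positive number (nm/px)")
  fmt <- match.arg(source_format,
                   c("nanoscope", "jpk", "ibw", "ascii", "raster", "synthetic"))
  heights <- matrix(as.numeric(heights), nrow(heights), ncol(heights))
  structure(list(heights = heights,
                 pixel_size_x = as.numeric(pixel_size_x),
                 pixel_size_y = as.numeric(pixel_size_y),
                 source_format = fmt,
                 source_path = as.character(source_path),
                 channel_name = channel_name),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %d x %d px, pixel %.4g x %.4g nm, format=%s\n",
              nrow(x$heights), ncol(x$heights),
              x$pixel_size_x, x$pixel_size_y, x$source_format))
  cat(sprintf("  height range [%.4g, %.4g] nm", min(x$heights), max(x$heights)))
  if (!is.null(x$channel_name)) cat("  channel:", x$channel_name)
  cat("\n")
  invisible(x)
}

#' @export
dim.height_map <- function(x) dim(x$heights)

#' @export
summary.height_map <- function(object, ...) {
  h <- object$heights
  out <- list(
    n_rows = nrow(h), n_cols = ncol(h),
    pixel_size_x = object$pixel_size_x, pixel_size_y = object$pixel_size_y,
    min_nm = min(h), max_nm = max(h), mean_nm = mean(h),
    scan_size_x_nm = ncol(h) * object$pixel_size_x,
    scan_size_y_nm = nrow(h) * object$pixel_size_y,
    source_format = object$source_format)
  class(out) <- "summary.height_map"
  out
}

#' @export
print.summary.height_map <- function(x, ...) {
  cat(sprintf("height map %d x %d px (%.4g x %.4g nm scan), format=%s\n",
              x$n_rows, x$n_cols, x$scan_size_y_nm, x$scan_size_x_nm,
              x$source_format))
  cat(sprintf("  pixel size: %.6g x %.6g nm/px\n", x$pixel_size_x, x$pixel_size_y))
  cat(sprintf("  heights: min %.4g, max %.4g, mean %.4g nm\n",
              x$min_nm, x$max_nm, x$mean_nm))
  invisible(x)
}

is_height_map <- function(x) inherits(x, "height_map")

assert_height_map <- function(x) {
  if (!is_height_map(x)) stop("expected a height_map object")
  invisible(x)
}

#' Rectangular sub-area selection
#'
#' Selections use 0-based, half-open pixel ranges: rows
#' `[row_start, row_end)` and columns `[col_start, col_end)`, with row 0
#' the top scan line. This matches raster storage order and is used by
#' every cropping interface, including the CLI `--crop r0 r1 c0 c1`.
#'
#' @param row_start,row_end,col_start,col_end 0-based half-open bounds.
#' @param label non-empty alphanumeric identifier for the selected complex.
#' @return an object of class `region_selection`.
#' @export
region_selection <- function(row_start, row_end, col_start, col_end,
                             label = "1") {
  v <- c(row_start, row_end, col_start, col_end)
  if (!is.numeric(v) || length(v) != 4L || any(!is.finite(v)) ||
      any(v != floor(v)))
    stop("selection bounds must be integers")
  if (!(row_start >= 0 && row_start < row_end))
    stop("need 0 <= row_start < row_end")
  if (!(col_start >= 0 && col_start < col_end))
    stop("need 0 <= col_start < col_end")
  label <- as.character(label)
  if (length(label) != 1L || !nzchar(label))
    stop("label must be a non-empty string")
  structure(list(row_start = as.integer(row_start),
                 row_end = as.integer(row_end),
                 col_start = as.integer(col_start),
                 col_end = as.integer(col_end),
                 label = label),
            class = "region_selection")
}

#' Crop a height map to a rectangular selection
#'
#' Returns the sub-grid copy; pixel sizes are unchanged. Out-of-bounds
#' selections are rejected with the offending index.
#'
#' @param map a [height_map()].
#' @param sel a [region_selection()].
#' @return a `height_map` covering the selected area.
#' @export
crop <- function(map, sel) {
  assert_height_map(map)
  if (!inherits(sel, "region_selection"))
    stop("sel must be a region_selection")
  nr <- nrow(map$heights); nc <- ncol(map$heights)
  if (sel$row_end > nr)
    stop(sprintf("selection row_end %d exceeds image rows %d", sel$row_end, nr))
  if (sel$col_end > nc)
    stop(sprintf("selection col_end %d exceeds image cols %d", sel$col_end, nc))
  sub <- map$heights[(sel$row_start + 1L):sel$row_end,
                     (sel$col_start + 1L):sel$col_end, drop = FALSE]
  if (nrow(sub) < 2L || ncol(sub) < 2L)
    stop("cropped area must be at least 2 x 2 pixels")
  out <- map
  out$heights <- sub
  out
}
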
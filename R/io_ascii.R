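#' Read an ASCII x-y-z table as a height map
#'
#' Accepts whitespace- or comma-delimited rows of `x y z`, optionally
#' preceded by any number of non-numeric header lines (the first fully
#' numeric row starts the data). The `(x, y)` points must form a complete
#' rectangular grid; `z` is taken as height in nm. Rows are ordered by
#' ascending `y` (top scan line first), columns by ascending `x`.
#'
#' @param path file to read.
#' @param pixel_size_nm optional override for the lateral calibration; by
#'   default the median x-spacing (and y-spacing) of the grid is used.
#' @return a [height_map()].
#' @export
read_ascii <- function(path, pixel_size_nm = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty ASCII file: ", path)
  parse_row <- function(s) {
    toks <- strsplit(trimws(s), "[,;[:space:]]+")[[1]]
    suppressWarnings(as.numeric(toks))
  }
  parsed <- lapply(lines, parse_row)
  numeric_row <- vapply(parsed, function(v)
    length(v) >= 3L && !anyNA(v[1:3]), logical(1))
  first <- which(numeric_row)[1]
  if (is.na(first)) stop("no numeric x y z rows found in ", path)
  dat <- parsed[seq(first, length(parsed))]
  if (!all(numeric_row[seq(first, length(parsed))]))
    stop("non-numeric row inside the data block of ", path)
  xyz <- do.call(rbind, dat)[, 1:3, drop = FALSE]

  ux <- sort(unique(xyz[, 1])); uy <- sort(unique(xyz[, 2]))
  nx <- length(ux); ny <- length(uy)
  if (nx < 2L || ny < 2L) stop("ASCII grid must span at least 2 x 2 points")
  if (nrow(xyz) != nx * ny)
    stop(sprintf(
      "x y points do not form a complete rectangular grid: %d points present, %d expected (%d missing)",
      nrow(xyz), nx * ny, abs(nx * ny - nrow(xyz))))
  ix <- match(xyz[, 1], ux); iy <- match(xyz[, 2], uy)
  h <- matrix(NA_real_, ny, nx)
  h[cbind(iy, ix)] <- xyz[, 3]
  if (anyNA(h))
    stop(sprintf("x y points do not form a complete rectangular grid: %d cells missing",
                 sum(is.na(h))))
  psx <- if (!is.null(pixel_size_nm)) pixel_size_nm else stats::median(diff(ux))
  psy <- if (!is.null(pixel_size_nm)) pixel_size_nm else stats::median(diff(uy))
  height_map(h, psx, psy, source_format = "ascii", source_path = path)
}

#' Read a generic raster image (TIFF/JPEG/PNG) as a height map
#'
#' Plain rasters carry no physical calibration, so both the vertical scale
#' (nm per intensity unit, where one unit is one grey level of the file's
#' bit depth) and the lateral pixel size must be supplied. RGB images are
#' collapsed to grey by luminance (0.2126 R + 0.7152 G + 0.0722 B) with a
#' warning; these files are convenience inputs, not metrology-grade.
#'
#' @param path TIFF, JPEG or PNG file.
#' @param height_scale_nm_per_unit nm of height per grey level.
#' @param pixel_size_nm lateral calibration, nm/px. Required; never
#'   silently assumed.
#' @return a [height_map()].
#' @export
read_raster <- function(path, height_scale_nm_per_unit, pixel_size_nm) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (missing(pixel_size_nm) || is.null(pixel_size_nm))
    stop("pixel_size_nm is required: raster files carry no lateral calibration")
  if (missing(height_scale_nm_per_unit) || is.null(height_scale_nm_per_unit))
    stop("height_scale_nm_per_unit is required: raster files carry no height calibration")
  magic <- readBin(path, "raw", n = 25L)
  if (length(magic) >= 4L &&
      identical(as.integer(magic[1:2]), c(0xffL, 0xd8L))) {
    img <- jpeg::readJPEG(path)
    bits <- 8L
  } else if (length(magic) >= 4L &&
             identical(as.integer(magic[1:4]), c(0x89L, 0x50L, 0x4eL, 0x47L))) {
    img <- png::readPNG(path)
    bits <- as.integer(magic[25L])    # bit-depth byte of the IHDR chunk
  } else if (length(magic) >= 2L &&
             (identical(rawToChar(magic[1:2]), "II") ||
              identical(rawToChar(magic[1:2]), "MM"))) {
    img <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(img, "bits.per.sample")
    if (is.null(bits)) {
      raw_img <- tiff::readTIFF(path, as.is = TRUE)
      bits <- if (max(raw_img) > 255) 16L else 8L
      img <- raw_img / (2^bits - 1)
    }
  } else stop("unrecognized raster file (not TIFF/JPEG/PNG): ", path)

  if (is.array(img) && length(dim(img)) == 3L) {
    nchan <- dim(img)[3]
    if (nchan >= 3L) {
      warning("RGB raster converted to gray by luminance: ", path)
      img <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    } else img <- img[, , 1]
  }
  # readers return intensities in [0,1]; express in native grey levels
  units <- img * (2^bits - 1)
  height_map(units * height_scale_nm_per_unit,
             pixel_size_nm, pixel_size_nm,
             source_format = "raster", source_path = path)
}
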
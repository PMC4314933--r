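#' Load an SFM image of any supported dialect
#'
#' Dispatch precedence: explicit `format_hint` first, then file magic
#' bytes, then the file extension. A TIFF container carrying JPK private
#' calibration tags is routed to the JPK reader; a plain TIFF falls back
#' to [read_raster()] (which then requires calibration arguments).
#'
#' @param path file to load.
#' @param format_hint optional, one of `"nanoscope"`, `"jpk"`, `"ibw"`,
#'   `"ascii"`, `"raster"`.
#' @param ... passed to the dialect reader (e.g. `pixel_size_nm` for
#'   ASCII or raster files).
#' @return a [height_map()].
#' @export
load_any <- function(path, format_hint = NULL, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!is.null(format_hint)) {
    fmt <- match.arg(format_hint,
                     c("nanoscope", "jpk", "ibw", "ascii", "raster"))
    return(switch(fmt,
                  nanoscope = read_nanoscope(path),
                  jpk = read_jpk(path),
                  ibw = read_ibw(path),
                  ascii = read_ascii(path, ...),
                  raster = read_raster(path, ...)))
  }
  fmt <- detect_format(path)
  if (is.na(fmt))
    stop("cannot determine the format of '", path,
         "'; supported dialects: nanoscope, jpk, ibw, ascii, raster ",
         "(tiff/jpeg/png)")
  load_any(path, format_hint = fmt, ...)
}

# magic-byte / extension sniffing; returns a dialect name or NA
detect_format <- function(path) {
  magic <- readBin(path, "raw", n = 16L)
  n <- length(magic)
  if (n >= 11L && identical(magic[1:11], charToRaw("\\*File list")))
    return("nanoscope")
  if (n >= 4L && identical(as.integer(magic[1:4]),
                           c(0x89L, 0x50L, 0x4eL, 0x47L)))
    return("raster")
  if (n >= 2L && identical(as.integer(magic[1:2]), c(0xffL, 0xd8L)))
    return("raster")
  if (n >= 4L && (identical(rawToChar(magic[1:2]), "II") ||
                  identical(rawToChar(magic[1:2]), "MM"))) {
    # TIFF container: JPK if the private calibration tags are present
    jpk <- tryCatch({
      tf <- tiff_read_ifds(path)
      ifd <- tf$ifds[[length(tf$ifds)]]
      jpk_calibration(ifd)
      TRUE
    }, error = function(e) FALSE)
    return(if (jpk) "jpk" else "raster")
  }
  ext <- tolower(tools::file_ext(path))
  if (n >= 2L &&
      readBin(magic[1:2], "integer", size = 2L, endian = "little") == 5L &&
      ext == "ibw")
    return("ibw")
  if (ext == "ibw") return("ibw")
  if (ext %in% c("txt", "asc", "csv", "xyz", "dat")) return("ascii")
  # last resort: a text file that parses as x-y-z data
  head_txt <- tryCatch(readLines(path, n = 5L, warn = FALSE),
                       error = function(e) character())
  if (length(head_txt) > 0L &&
      isTRUE(all(vapply(head_txt, function(s)
        isTRUE(all(utf8ToInt(substr(s, 1, 200)) < 128)), logical(1)))))
    return("ascii")
  NA_character_
}

#' One-line description of an SFM image file
#'
#' Backs the CLI `info` subcommand: detects the dialect, loads the file
#' and reports dimensions, pixel size and the height range.
#'
#' @inheritParams load_any
#' @return invisibly, the loaded [height_map()].
#' @export
describe_file <- function(path, format_hint = NULL, ...) {
  map <- load_any(path, format_hint = format_hint, ...)
  s <- summary(map)
  cat(sprintf("%s: %s, %d x %d px, pixel %.6g x %.6g nm, height [%.4g, %.4g] nm\n",
              path, map$source_format, s$n_rows, s$n_cols,
              s$pixel_size_x, s$pixel_size_y, s$min_nm, s$max_nm))
  invisible(map)
}
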
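# NanoScope v5.x dialect: ASCII header block of "\Key: value" lines
# delimited by "\*File list" ... "\*File list end", followed by 16-bit
# little-endian binary image data at the stated data offset. Height
# calibration follows the v5 convention
#   height_nm = raw * Zscale_V * Zsens_nm_per_V / 2^16
# with both factors taken from the header. Other header versions are
# rejected rather than guessed at.

parse_nanoscope_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) break
    hdr <- c(hdr, line)
    if (grepl("^\\\\\\*File list end", line)) break
    if (length(hdr) > 10000L) break
  }
  hdr
}

ns_value <- function(hdr, key) {
  pat <- paste0("^\\\\@?", gsub("([][(){}.*+?^$|\\\\])", "\\\\\\1", key), ":")
  hit <- grep(pat, hdr, value = TRUE)
  if (length(hit) == 0L) return(NULL)
  sub(pat, "", hit[1L])
}

ns_trailing_number <- function(s) {
  m <- regmatches(s, gregexpr("[-+0-9.eE]+", s))[[1]]
  m <- suppressWarnings(as.numeric(m))
  m <- m[!is.na(m)]
  if (length(m) == 0L) return(NA_real_)
  m[length(m)]
}

#' Read a NanoScope v5 SFM image
#'
#' Parses the text header, extracts the scan size and the two vertical
#' calibration factors (Z scale in volts and the Z sensitivity in nm/V),
#' and decodes the 16-bit little-endian height channel. Pixel size is
#' scan size divided by the pixel count per axis. Header versions other
#' than 5.x are rejected.
#'
#' @param path NanoScope file.
#' @return a [height_map()].
#' @export
read_nanoscope <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readBin(path, "raw", n = 12L)
  if (!identical(rawToChar(first[1:11]), "\\*File list"))
    stop("not a NanoScope file (missing '\\*File list' header magic): ", path)
  hdr <- parse_nanoscope_header(path)

  ver <- ns_value(hdr, "Version")
  if (!is.null(ver) && !grepl("^\\s*0x0?5", ver))
    stop("unsupported NanoScope header version (only v5.x is handled): ",
         trimws(ver))

  need <- function(key) {
    v <- ns_value(hdr, key)
    if (is.null(v))
      stop("NanoScope calibration entry missing from header: '", key, "'")
    v
  }
  scan_raw <- need("Scan Size")
  nums <- suppressWarnings(as.numeric(
    regmatches(scan_raw, gregexpr("[-+0-9.eE]+", scan_raw))[[1]]))
  nums <- nums[!is.na(nums)]
  if (length(nums) == 0L) stop("NanoScope 'Scan Size' entry is not numeric")
  scan_x <- nums[1L]
  scan_y <- if (length(nums) >= 2L) nums[2L] else nums[1L]
  if (grepl("\\bum\\b|\\bµm\\b", scan_raw)) {
    scan_x <- scan_x * 1000; scan_y <- scan_y * 1000
  }

  samps <- as.integer(ns_trailing_number(need("Samps/line")))
  lines_n <- as.integer(ns_trailing_number(need("Number of lines")))
  offset <- as.integer(ns_trailing_number(need("Data offset")))
  zscale <- ns_trailing_number(need("2:Z scale"))
  zsens <- ns_trailing_number(need("Sens. Zsens"))
  if (!is.finite(zscale)) stop("NanoScope calibration entry missing from header: '2:Z scale'")
  if (!is.finite(zsens)) stop("NanoScope calibration entry missing from header: 'Sens. Zsens'")

  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, offset)
  raw <- readBin(con, "integer", n = samps * lines_n, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < samps * lines_n)
    stop("NanoScope image data truncated: ", path)
  h <- matrix(raw * zscale * zsens / 65536, nrow = lines_n, ncol = samps,
              byrow = TRUE)
  height_map(h, scan_x / samps, scan_y / lines_n,
             source_format = "nanoscope", source_path = path,
             channel_name = "Height")
}

# Fixture writer for the NanoScope dialect (test/dev API; see
# write_fixture). Chooses a Z scale that spans the data range so the
# 16-bit quantization step is (zscale * zsens / 2^16) nm.
write_nanoscope_fixture <- function(map, path, zsens_nm_per_v = 12.5) {
  assert_height_map(map)
  h <- map$heights
  nr <- nrow(h); nc <- ncol(h)
  maxabs <- max(abs(h))
  zscale <- if (maxabs == 0) 1 else maxabs * 65536 / (32000 * zsens_nm_per_v)
  raw <- as.integer(round(h * 65536 / (zscale * zsens_nm_per_v)))
  offset <- 2048L
  hdr <- c(
    "\\*File list",
    "\\Version: 0x05300002",
    sprintf("\\@Sens. Zsens: V %.9f nm/V", zsens_nm_per_v),
    "\\*Ciao image list",
    sprintf("\\Data offset: %d", offset),
    sprintf("\\Data length: %d", 2L * nr * nc),
    sprintf("\\Samps/line: %d", nc),
    sprintf("\\Number of lines: %d", nr),
    sprintf("\\Scan Size: %.9g %.9g nm", nc * map$pixel_size_x,
            nr * map$pixel_size_y),
    sprintf("\\@2:Z scale: V (%.10g V/LSB) %.10g V", zscale / 65536, zscale),
    "\\Image Data: Height",
    "\\*File list end")
  con <- file(path, "wb")
  on.exit(close(con))
  txt <- paste0(paste(hdr, collapse = "\r\n"), "\r\n")
  writeBin(charToRaw(txt), con)
  pad <- offset - nchar(txt, type = "bytes")
  if (pad < 0) stop("NanoScope fixture header exceeds data offset")
  writeBin(rep(as.raw(0L), pad), con)
  writeBin(as.integer(t(raw_matrix <- matrix(raw, nr, nc))), con,
           size = 2L, endian = "little")
  invisible(path)
}
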
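# Fixture writers: minimal, spec-conformant files in every dialect the
# package reads, so each reader is exercisable end-to-end without
# external data. Test/dev API -- deliberately not part of the CLI, to
# avoid implying vendor-format authoring support.

#' Write a height map as a minimal fixture file in a given dialect
#'
#' Produces a file the corresponding reader accepts. Quantization bounds
#' per dialect: `ascii`/`ascii_header` are exact to the printed
#' precision (10 significant digits); `nanoscope`, `jpk`, `tiff` and
#' `png` quantize to 16 bits (step = data range / 65535, or the Z-scale
#' LSB for nanoscope); `ibw` stores IEEE doubles (exact); `jpeg` is
#' 8-bit and lossy, so only high correlation survives a round-trip.
#'
#' @param map a [height_map()].
#' @param dialect one of `"nanoscope"`, `"jpk"`, `"ibw"`, `"ascii"`,
#'   `"ascii_header"`, `"tiff"`, `"jpeg"`, `"png"`.
#' @param path output file.
#' @param ... dialect-specific options (e.g. `layout` for jpk,
#'   `extra_layers` for ibw).
#' @return invisibly, a list with `path`, `dialect` and the calibration
#'   needed to read rasters back (`height_scale_nm_per_unit`,
#'   `offset_nm`, `pixel_size_nm`); plain-format readers need no
#'   calibration and ignore it.
#' @export
write_fixture <- function(map, dialect = c("nanoscope", "jpk", "ibw",
                                           "ascii", "ascii_header",
                                           "tiff", "jpeg", "png"),
                          path, ...) {
  assert_height_map(map)
  dialect <- match.arg(dialect)
  h <- map$heights
  info <- list(path = path, dialect = dialect,
               height_scale_nm_per_unit = NA_real_, offset_nm = 0,
               pixel_size_nm = map$pixel_size_x)
  switch(dialect,
    nanoscope = write_nanoscope_fixture(map, path),
    jpk = write_jpk_fixture(map, path, ...),
    ibw = write_ibw_fixture(map, path, ...),
    ascii = write_ascii_fixture(map, path, header = FALSE),
    ascii_header = write_ascii_fixture(map, path, header = TRUE),
    tiff = ,
    jpeg = ,
    png = {
      rng <- range(h)
      span <- diff(rng)
      bits <- if (dialect == "jpeg") 8L else 16L
      levels <- 2^bits - 1
      scale <- if (span == 0) 1 else span / levels
      units <- round((h - rng[1]) / scale)
      info$height_scale_nm_per_unit <- scale
      info$offset_nm <- rng[1]
      if (dialect == "tiff") {
        tiff::writeTIFF(units / levels, path, bits.per.sample = 16L)
      } else if (dialect == "jpeg") {
        jpeg::writeJPEG(units / levels, path, quality = 0.98)
      } else {
        write_png16(as.integer(round(units)), nrow(h), ncol(h), path)
      }
    })
  invisible(info)
}

write_ascii_fixture <- function(map, path, header = FALSE) {
  h <- map$heights
  nr <- nrow(h); nc <- ncol(h)
  rows <- expand.grid(row = 0:(nr - 1), col = 0:(nc - 1))
  lines <- sprintf("%s %s %s",
                   fmt_num(rows$col * map$pixel_size_x),
                   fmt_num(rows$row * map$pixel_size_y),
                   fmt_num(h[cbind(rows$row + 1L, rows$col + 1L)]))
  if (header)
    lines <- c("# synthetic SFM height map fixture",
               "# x_nm y_nm z_nm", lines)
  writeLines(lines, path)
  invisible(path)
}

# --- minimal 16-bit grayscale PNG encoder --------------------------------
# (the installed png/EBImage writers emit 8-bit only; png::readPNG reads
# 16-bit natively, so fixtures use this tiny encoder)

png_crc_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    t <- integer(256)
    for (n in 0:255) {
      c <- n
      for (k in 1:8)
        c <- if (bitwAnd(c, 1L) == 1L)
          bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1))  # 0xEDB88320
        else bitwShiftR(bitwAnd(c, -2L), 1)
      t[n + 1] <- c
    }
    tab <<- t
    tab
  }
})

png_crc32 <- function(bytes) {
  tab <- png_crc_table()
  crc <- -1L
  v <- as.integer(bytes)
  for (b in v)
    crc <- bitwXor(tab[bitwAnd(bitwXor(crc, b), 255L) + 1L],
                   bitwShiftR(bitwAnd(crc, -256L), 8))
  bitwXor(crc, -1L)
}

be32 <- function(x) {
  x <- as.numeric(x) %% 2^32
  as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(be32(length(data)), body, be32(png_crc32(body)))
}

write_png16 <- function(units, nr, nc, path) {
  if (any(units < 0L | units > 65535L))
    stop("16-bit PNG fixture: values outside [0, 65535]")
  m <- matrix(units, nr, nc)
  # scanlines: filter byte 0 + big-endian 16-bit samples
  scan <- raw((2L * nc + 1L) * nr)
  pos <- 1L
  for (r in seq_len(nr)) {
    v <- m[r, ]
    row_bytes <- as.raw(rbind(v %/% 256L, v %% 256L))
    scan[pos] <- as.raw(0L)
    scan[(pos + 1L):(pos + 2L * nc)] <- row_bytes
    pos <- pos + 2L * nc + 1L
  }
  ihdr <- c(be32(nc), be32(nr), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", memCompress(scan, type = "gzip")),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}
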
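# JPK-dialect TIFF: a standard little-endian TIFF 6.0 container with two
# pages (page 1 a small thumbnail, page 2 the full scan) and private IFD
# tags carrying the height calibration, applied as
#   calibrated = offset + multiplier * raw        (result in nm)
# Two tag layouts exist, mirroring the generation change in the vendor
# software: in the older layout the multiplier/offset doubles sit at tags
# 32835/32836; in the newer one an ASCII channel-name tag occupies 32835
# and the doubles shift to 32836/32837. Scan dimensions (nm) are at
# 32833 (x) and 32834 (y) in both layouts. The reader tries both layouts
# and reports an error naming them if neither matches.
#
# Only the features the dialect needs are implemented: little-endian,
# uncompressed, single-strip, grayscale 8/16-bit pages. No installed R
# package exposes private TIFF tags, hence the explicit IFD walk.

JPK_TAG_SCAN_X <- 32833L
JPK_TAG_SCAN_Y <- 32834L

tiff_read_ifds <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file (too short): ", path)
  order_tag <- rawToChar(raw[1:2])
  if (!identical(order_tag, "II"))
    stop("JPK reader handles little-endian ('II') TIFF only: ", path)
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer", size = 2,
                               signed = FALSE, endian = "little")
  u32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer", size = 4,
                               endian = "little")
  if (u16(2) != 42L) stop("bad TIFF magic number in ", path)
  ifds <- list()
  off <- u32(4)
  while (off != 0L && length(ifds) < 16L) {
    n <- u16(off)
    entries <- list()
    for (i in seq_len(n)) {
      e <- off + 2 + (i - 1) * 12
      tag <- u16(e); type <- u16(e + 2); count <- u32(e + 4)
      type_size <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)[type]
      nbytes <- type_size * count
      voff <- if (nbytes <= 4) e + 8 else u32(e + 8)
      bytes <- raw[(voff + 1):(voff + nbytes)]
      value <- switch(as.character(type),
        "1" = as.integer(bytes),
        "2" = rawToChar(bytes[bytes != as.raw(0)]),
        "3" = readBin(bytes, "integer", n = count, size = 2,
                      signed = FALSE, endian = "little"),
        "4" = readBin(bytes, "integer", n = count, size = 4,
                      endian = "little"),
        "11" = readBin(bytes, "double", n = count, size = 4,
                       endian = "little"),
        "12" = readBin(bytes, "double", n = count, size = 8,
                       endian = "little"),
        bytes)
      entries[[as.character(tag)]] <- list(type = type, value = value)
    }
    ifds[[length(ifds) + 1L]] <- entries
    off <- u32(off + 2 + n * 12)
  }
  list(raw = raw, ifds = ifds)
}

tiff_page_matrix <- function(raw, ifd) {
  g <- function(tag, default = NULL) {
    e <- ifd[[as.character(tag)]]
    if (is.null(e)) default else e$value
  }
  width <- g(256); height <- g(257)
  bits <- g(258, 8L)[1]
  comp <- g(259, 1L)
  if (comp != 1L) stop("JPK dialect pages must be uncompressed")
  strip_off <- g(273); strip_cnt <- g(279)
  if (length(strip_off) != 1L) stop("JPK dialect pages must be single-strip")
  bytes <- raw[(strip_off + 1):(strip_off + strip_cnt)]
  vals <- if (bits == 16L)
    readBin(bytes, "integer", n = width * height, size = 2,
            signed = FALSE, endian = "little")
  else as.integer(bytes)
  matrix(vals, nrow = height, ncol = width, byrow = TRUE)
}

jpk_calibration <- function(ifd) {
  getd <- function(tag) {
    e <- ifd[[as.character(tag)]]
    if (!is.null(e) && e$type == 12L) e$value[1] else NULL
  }
  m_old <- getd(32835L); o_old <- getd(32836L)
  if (!is.null(m_old) && !is.null(o_old) &&
      is.null(getd(32837L)))                       # old layout: no third double
    return(list(multiplier = m_old, offset = o_old, layout = "pre-4.2.53"))
  m_new <- getd(32836L); o_new <- getd(32837L)
  if (!is.null(m_new) && !is.null(o_new))
    return(list(multiplier = m_new, offset = o_new, layout = "v4.2.53"))
  stop("JPK calibration tags not found: tried layouts pre-4.2.53 ",
       "(multiplier/offset at 32835/32836) and v4.2.53 (32836/32837)")
}

#' Read a JPK-dialect TIFF SFM image
#'
#' Skips the thumbnail page, decodes the full-resolution second page and
#' applies the linear calibration `offset + multiplier * raw` (result in
#' nm) taken from the JPK private tags. Both documented tag layouts are
#' tried; pixel size comes from the stored scan dimensions.
#'
#' @param path JPK TIFF file.
#' @return a [height_map()].
#' @export
read_jpk <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tf <- tiff_read_ifds(path)
  if (length(tf$ifds) == 0L) stop("no TIFF pages found in ", path)
  # the first page is a thumbnail of the second; use the last (full) page
  ifd <- tf$ifds[[length(tf$ifds)]]
  cal <- jpk_calibration(ifd)
  m <- tiff_page_matrix(tf$raw, ifd)
  h <- cal$offset + cal$multiplier * m
  gs <- function(tag) {
    e <- ifd[[as.character(tag)]]
    if (is.null(e)) NULL else e$value[1]
  }
  scan_x <- gs(JPK_TAG_SCAN_X); scan_y <- gs(JPK_TAG_SCAN_Y)
  if (is.null(scan_x) || is.null(scan_y))
    stop("JPK scan-dimension tags (32833/32834) missing; cannot calibrate pixel size")
  chan <- gs(32835L)
  height_map(h, scan_x / ncol(m), scan_y / nrow(m),
             source_format = "jpk", source_path = path,
             channel_name = if (is.character(chan)) chan else NULL)
}

# --- minimal TIFF writer for the JPK fixture dialect (test/dev API) ----

tiff_entry <- function(tag, type, count, value_bytes) {
  list(tag = tag, type = type, count = count, bytes = value_bytes)
}

le16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
le32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
le_dbl <- function(x) writeBin(as.double(x), raw(), size = 8, endian = "little")

# Serialize pages (list of: entries list + strip raw data) into one TIFF.
tiff_write_pages <- function(pages, path) {
  header_len <- 8L
  # layout: header | for each page: [strip data][out-of-line values][IFD]
  blobs <- raw(0)
  offset <- header_len
  ifd_offsets <- integer(length(pages))
  for (p in seq_along(pages)) {
    page <- pages[[p]]
    strip_off <- offset
    blobs <- c(blobs, page$strip)
    offset <- offset + length(page$strip)
    # resolve strip offset tag now
    entries <- page$entries
    entries[["273"]] <- tiff_entry(273L, 4L, 1L, le32(strip_off))
    entries[["279"]] <- tiff_entry(279L, 4L, 1L, le32(length(page$strip)))
    tags <- sort(as.integer(names(entries)))
    # out-of-line values
    for (tg in tags) {
      e <- entries[[as.character(tg)]]
      if (length(e$bytes) > 4L) {
        if (offset %% 2L == 1L) { blobs <- c(blobs, as.raw(0)); offset <- offset + 1L }
        entries[[as.character(tg)]]$voff <- offset
        blobs <- c(blobs, e$bytes)
        offset <- offset + length(e$bytes)
      }
    }
    if (offset %% 2L == 1L) { blobs <- c(blobs, as.raw(0)); offset <- offset + 1L }
    ifd_offsets[p] <- offset
    ifd <- le16(length(tags))
    for (tg in tags) {
      e <- entries[[as.character(tg)]]
      vb <- if (length(e$bytes) > 4L) le32(e$voff)
            else c(e$bytes, rep(as.raw(0), 4L - length(e$bytes)))
      ifd <- c(ifd, le16(e$tag), le16(e$type), le32(e$count), vb)
    }
    ifd <- c(ifd, le32(0L))  # next-IFD placeholder, patched below
    blobs <- c(blobs, ifd)
    offset <- offset + length(ifd)
  }
  out <- c(charToRaw("II"), le16(42L), le32(ifd_offsets[1]), blobs)
  # patch next-IFD pointers
  for (p in seq_len(length(pages) - 1L)) {
    n <- readBin(out[(ifd_offsets[p] + 1):(ifd_offsets[p] + 2)], "integer",
                 size = 2, signed = FALSE, endian = "little")
    ptr_pos <- ifd_offsets[p] + 2L + n * 12L
    out[(ptr_pos + 1):(ptr_pos + 4)] <- le32(ifd_offsets[p + 1])
  }
  writeBin(out, path)
  invisible(path)
}

# Write a JPK-dialect fixture: thumbnail page + calibrated 16-bit page.
# multiplier/offset default to spanning the data range (quantization step
# = range/65535); layout selects the private-tag generation.
write_jpk_fixture <- function(map, path, layout = c("pre-4.2.53", "v4.2.53"),
                              multiplier = NULL, offset = NULL) {
  assert_height_map(map)
  layout <- match.arg(layout)
  h <- map$heights
  if (is.null(multiplier) || is.null(offset)) {
    rng <- range(h)
    offset <- rng[1]
    multiplier <- if (diff(rng) == 0) 1 else diff(rng) / 65535
  }
  raw_vals <- as.integer(round((h - offset) / multiplier))
  if (any(raw_vals < 0 | raw_vals > 65535))
    stop("JPK fixture: heights do not fit the 16-bit range with the given calibration")

  base_entries <- function(width, height, bits) {
    e <- list()
    e[["256"]] <- tiff_entry(256L, 4L, 1L, le32(width))
    e[["257"]] <- tiff_entry(257L, 4L, 1L, le32(height))
    e[["258"]] <- tiff_entry(258L, 3L, 1L, le16(bits))
    e[["259"]] <- tiff_entry(259L, 3L, 1L, le16(1L))
    e[["262"]] <- tiff_entry(262L, 3L, 1L, le16(1L))   # BlackIsZero
    e[["277"]] <- tiff_entry(277L, 3L, 1L, le16(1L))
    e[["278"]] <- tiff_entry(278L, 4L, 1L, le32(height))
    e
  }
  # thumbnail: 8-bit down-scaled preview (or full size if already tiny)
  th_nr <- min(nrow(h), 8L); th_nc <- min(ncol(h), 8L)
  ri <- unique(pmax(1L, round(seq(1, nrow(h), length.out = th_nr))))
  ci <- unique(pmax(1L, round(seq(1, ncol(h), length.out = th_nc))))
  th <- h[ri, ci, drop = FALSE]
  rng <- range(th)
  th8 <- if (diff(rng) == 0) matrix(0L, nrow(th), ncol(th))
         else matrix(as.integer(round((th - rng[1]) / diff(rng) * 255)),
                     nrow(th), ncol(th))
  page1 <- list(entries = base_entries(ncol(th8), nrow(th8), 8L),
                strip = as.raw(as.integer(t(th8))))

  e2 <- base_entries(ncol(h), nrow(h), 16L)
  e2[[as.character(JPK_TAG_SCAN_X)]] <-
    tiff_entry(JPK_TAG_SCAN_X, 12L, 1L, le_dbl(ncol(h) * map$pixel_size_x))
  e2[[as.character(JPK_TAG_SCAN_Y)]] <-
    tiff_entry(JPK_TAG_SCAN_Y, 12L, 1L, le_dbl(nrow(h) * map$pixel_size_y))
  if (layout == "pre-4.2.53") {
    e2[["32835"]] <- tiff_entry(32835L, 12L, 1L, le_dbl(multiplier))
    e2[["32836"]] <- tiff_entry(32836L, 12L, 1L, le_dbl(offset))
  } else {
    nm <- c(charToRaw("Height"), as.raw(0))
    e2[["32835"]] <- tiff_entry(32835L, 2L, length(nm), nm)
    e2[["32836"]] <- tiff_entry(32836L, 12L, 1L, le_dbl(multiplier))
    e2[["32837"]] <- tiff_entry(32837L, 12L, 1L, le_dbl(offset))
  }
  strip2 <- writeBin(as.integer(t(matrix(raw_vals, nrow(h), ncol(h)))),
                     raw(), size = 2, endian = "little")
  page2 <- list(entries = e2, strip = strip2)
  tiff_write_pages(list(page1, page2), path)
}
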
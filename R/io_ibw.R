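# Igor binary wave, format version 5 (the dialect Asylum Research SFM
# controllers export). Implemented subset: uncompressed FP32/FP64 2-D or
# 3-D waves, little-endian, with per-dimension scaling (sfA deltas) and
# optional dimension labels used to pick the height channel of a
# multi-layer wave. File layout: 64-byte BinHeader5, 320-byte
# WaveHeader5, then data, then the optional dependency/note/units/label
# blocks in their canonical order.

IBW_BINHEADER_SIZE <- 64L
IBW_WAVEHEADER_SIZE <- 320L

ibw_unit_to_nm <- function(unit) {
  u <- trimws(unit)
  if (!nzchar(u)) return(1)  # unlabelled waves are taken as nm already
  switch(u,
         "m" = 1e9,
         "um" = 1e3,
         "nm" = 1,
         stop("unsupported Igor wave unit: '", u, "'"))
}

#' Read an Igor binary wave (IBW v5) SFM image
#'
#' Decodes a 2-D wave (or one layer of a 3-D multi-channel wave) with its
#' per-axis scaling. Layer choice for 3-D waves: the first layer whose
#' dimension label contains "height" (case-insensitive) wins, otherwise
#' layer 0 is used. Heights and axis deltas are converted to nm from the
#' wave's stored units (m, um, nm; unlabelled waves are taken as nm).
#'
#' @param path `.ibw` file.
#' @return a [height_map()].
#' @export
read_ibw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < IBW_BINHEADER_SIZE + IBW_WAVEHEADER_SIZE)
    stop("not an Igor binary wave (file too short): ", path)
  rd <- function(off, what, n = 1L, size = NA_integer_, signed = TRUE)
    readBin(raw[(off + 1):length(raw)], what, n = n, size = size,
            signed = signed, endian = "little")
  version <- rd(0L, "integer", size = 2L)
  if (version != 5L)
    stop("unsupported Igor binary wave version ", version,
         " (only version 5 is handled)")
  i32 <- function(off) rd(off, "integer", size = 4L)
  dimEUnitsSize <- vapply(0:3, function(k) i32(16L + 4L * k), integer(1))
  dimLabelsSize <- vapply(0:3, function(k) i32(32L + 4L * k), integer(1))
  formulaSize <- i32(8L); noteSize <- i32(12L)
  dataEUnitsSize <- i32(48L)

  wh <- IBW_BINHEADER_SIZE
  npnts <- i32(wh + 12L)
  type <- rd(wh + 16L, "integer", size = 2L)
  cstr <- function(b) rawToChar(b[b != as.raw(0)])
  bname <- cstr(raw[(wh + 28L + 1L):(wh + 28L + 32L)])
  nDim <- vapply(0:3, function(k) i32(wh + 64L + 4L * k), integer(1))
  sfA <- vapply(0:3, function(k) rd(wh + 80L + 8L * k, "double", size = 8L),
                numeric(1))
  data_units <- trimws(cstr(raw[(wh + 144L + 1L):(wh + 144L + 4L)]))
  dim_units <- vapply(0:3, function(k)
    trimws(cstr(raw[(wh + 148L + 4L * k + 1L):(wh + 148L + 4L * k + 4L)])),
    character(1))

  ndims <- sum(nDim > 0L)
  if (ndims < 2L)
    stop("Igor wave '", bname, "' is ", ndims,
         "-dimensional; no 2-D height channel to select")
  elt_size <- switch(as.character(type), "2" = 4L, "4" = 8L,
                     stop("unsupported Igor wave numeric type ", type,
                          " (only FP32/FP64 are handled)"))
  data_off <- IBW_BINHEADER_SIZE + IBW_WAVEHEADER_SIZE
  vals <- rd(data_off, "double", n = npnts, size = elt_size)
  if (length(vals) < npnts) stop("Igor wave data truncated: ", path)

  nx <- nDim[1]; ny <- nDim[2]
  nlayers <- max(1L, nDim[3])
  # dimension labels live after data/formula/note/units blocks
  layer_labels <- rep("", nlayers)
  if (nlayers > 1L && dimLabelsSize[3] > 0L) {
    off <- data_off + npnts * elt_size + formulaSize + noteSize +
      dataEUnitsSize + sum(dimEUnitsSize) + dimLabelsSize[1] + dimLabelsSize[2]
    n_entries <- dimLabelsSize[3] %/% 32L
    labs <- vapply(seq_len(n_entries), function(k) {
      b <- raw[(off + (k - 1L) * 32L + 1L):(off + k * 32L)]
      trimws(rawToChar(b[b != as.raw(0)]))
    }, character(1))
    # entry 1 names the whole dimension; entries 2.. name the layers
    if (n_entries >= 2L)
      layer_labels[seq_len(min(nlayers, n_entries - 1L))] <-
        labs[2:min(n_entries, nlayers + 1L)]
  }
  layer <- 1L
  hit <- grep("height", layer_labels, ignore.case = TRUE)
  if (length(hit) > 0L) layer <- hit[1L]

  plane <- nx * ny
  layer_vals <- vals[((layer - 1L) * plane + 1L):(layer * plane)]
  # Igor stores dimension 0 fastest; dim 0 = x (columns), dim 1 = y (rows)
  h <- t(matrix(layer_vals, nrow = nx, ncol = ny))
  z_to_nm <- ibw_unit_to_nm(data_units)
  psx <- sfA[1] * ibw_unit_to_nm(dim_units[1])
  psy <- sfA[2] * ibw_unit_to_nm(dim_units[2])
  height_map(h * z_to_nm, psx, psy,
             source_format = "ibw", source_path = path,
             channel_name = if (nzchar(layer_labels[layer]))
               layer_labels[layer] else bname)
}

# Fixture writer (test/dev API; see write_fixture). Writes an FP64 v5
# wave; `extra_layers` prepends/appends flat dummy layers with labels so
# channel selection is exercisable. `units` = "m" stores heights and
# deltas in metres, "nm" stores them as nm.
write_ibw_fixture <- function(map, path, units = c("m", "nm"),
                              layer_labels = NULL, height_layer = 1L,
                              extra_layers = 0L, name = "HeightRetrace") {
  assert_height_map(map)
  units <- match.arg(units)
  scale <- if (units == "m") 1e-9 else 1
  h <- map$heights
  nr <- nrow(h); nc <- ncol(h)
  nlayers <- 1L + extra_layers
  if (height_layer > nlayers) stop("height_layer exceeds layer count")
  layers <- lapply(seq_len(nlayers), function(k)
    if (k == height_layer) h * scale else matrix(0, nr, nc))
  if (is.null(layer_labels) && nlayers > 1L) {
    layer_labels <- sprintf("Channel%d", seq_len(nlayers))
    layer_labels[height_layer] <- "HeightTrace"
  }

  npnts <- nr * nc * nlayers
  data <- unlist(lapply(layers, function(m) as.vector(t(m))))  # x fastest

  pad_str <- function(s, n) {
    b <- charToRaw(s)
    if (length(b) > n) b <- b[seq_len(n)]
    c(b, rep(as.raw(0), n - length(b)))
  }
  wh <- raw(IBW_WAVEHEADER_SIZE)
  put <- function(buf, off, bytes) { buf[(off + 1):(off + length(bytes))] <- bytes; buf }
  wh <- put(wh, 12L, le32(npnts))
  wh <- put(wh, 16L, le16(4L))                        # NT_FP64
  wh <- put(wh, 26L, le16(1L))                        # whVersion
  wh <- put(wh, 28L, pad_str(name, 32L))
  nDim <- c(nc, nr, if (nlayers > 1L) nlayers else 0L, 0L)
  wh <- put(wh, 64L, le32(nDim))
  sfA <- c(map$pixel_size_x, map$pixel_size_y, 1, 1) *
    c(if (units == "m") 1e-9 else 1, if (units == "m") 1e-9 else 1, 1, 1)
  wh <- put(wh, 80L, le_dbl(c(sfA)))
  wh <- put(wh, 112L, le_dbl(c(0, 0, 0, 0)))          # sfB origins
  wh <- put(wh, 144L, pad_str(units, 4L))             # dataUnits
  wh <- put(wh, 148L, c(pad_str(units, 4L), pad_str(units, 4L),
                        pad_str("", 4L), pad_str("", 4L)))

  has_labels <- nlayers > 1L && !is.null(layer_labels)
  dimLabelsSize <- c(0L, 0L, if (has_labels) (nlayers + 1L) * 32L else 0L, 0L)

  bh <- raw(IBW_BINHEADER_SIZE)
  bh <- put(bh, 0L, le16(5L))                          # version
  wfmSize <- IBW_WAVEHEADER_SIZE + npnts * 8L
  bh <- put(bh, 4L, le32(wfmSize))
  bh <- put(bh, 32L, le32(dimLabelsSize))
  # checksum over BinHeader5 + WaveHeader5 as int16 sum == 0
  body <- c(bh, wh)
  s16 <- readBin(body, "integer", n = length(body) / 2L, size = 2L,
                 endian = "little")
  chk <- (-sum(s16)) %% 65536L
  bh <- put(bh, 2L, le16(chk))

  out <- c(bh, wh, writeBin(as.double(data), raw(), size = 8, endian = "little"))
  if (has_labels) {
    labs <- c("Layers", layer_labels)
    out <- c(out, unlist(lapply(labs, pad_str, n = 32L)))
  }
  writeBin(out, path)
  invisible(path)
}
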
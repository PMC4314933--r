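# internal numeric helpers shared across modules

# Bilinear interpolation of matrix m at fractional (row, col) positions
# given in 0-based pixel-centre coordinates. Positions must lie within
# [0, nrow-1] x [0, ncol-1]; callers are responsible for bounds checks.
bilinear <- function(m, row, col) {
  nr <- nrow(m); nc <- ncol(m)
  if (any(row < -1e-9 | row > nr - 1 + 1e-9 | col < -1e-9 | col > nc - 1 + 1e-9))
    stop("interpolation position outside the image grid")
  row <- pmin(pmax(row, 0), nr - 1)
  col <- pmin(pmax(col, 0), nc - 1)
  r0 <- pmin(floor(row), nr - 2); c0 <- pmin(floor(col), nc - 2)
  fr <- row - r0; fc <- col - c0
  i00 <- cbind(r0 + 1, c0 + 1); i01 <- cbind(r0 + 1, c0 + 2)
  i10 <- cbind(r0 + 2, c0 + 1); i11 <- cbind(r0 + 2, c0 + 2)
  (1 - fr) * (1 - fc) * m[i00] + (1 - fr) * fc * m[i01] +
    fr * (1 - fc) * m[i10] + fr * fc * m[i11]
}

# Pad a matrix by k pixels on every side with edge replication.
pad_replicate <- function(m, k = 1L) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rep(1L, k), seq_len(nr), rep(nr, k))
  ci <- c(rep(1L, k), seq_len(nc), rep(nc, k))
  m[ri, ci, drop = FALSE]
}

# 8-connected component labeling of a logical matrix.
# Returns an integer matrix (0 = background) with labels numbered by
# first occurrence in row-major (top-to-bottom, left-to-right) order,
# which makes the largest-particle tie-break deterministic.
label_components8 <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)                       # column-major linear indices
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(lab)
  pos <- integer(nr * nc)                  # linear index -> vertex id
  pos[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  co <- ((idx - 1L) %/% nr) + 1L
  edges <- NULL
  # four forward shift directions cover every 8-adjacency pair once
  for (d in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + d[1L]; c2 <- co + d[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    j <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- mask[j]
    if (!any(hit)) next
    from <- pos[idx[ok][hit]]
    to <- pos[j[hit]]
    edges <- c(edges, rbind(from, to))
  }
  if (is.null(edges)) {
    comp <- seq_along(idx)
  } else {
    g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2L, byrow = TRUE),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership[seq_along(idx)]
  }
  # renumber components by first appearance in row-major order
  ord <- order(r, co)
  first_seen <- comp[ord][!duplicated(comp[ord])]
  remap <- integer(max(comp))
  remap[first_seen] <- seq_along(first_seen)
  lab[idx] <- remap[comp]
  lab
}

# format a number for CSV/fixture output without scientific notation noise
fmt_num <- function(x, digits = 10) trimws(formatC(x, digits = digits, format = "g"))

# Bicubic (Keys cubic-convolution, a = -0.5) interpolation of matrix m
# at fractional 0-based (row, col) positions. Borders are padded by
# linear extrapolation. Used for cross-section sampling, where the
# sub-pixel broadening of bilinear interpolation would bias narrow
# Gaussian widths upward.
bicubic <- function(m, row, col) {
  nr <- nrow(m); nc <- ncol(m)
  if (any(row < -1e-9 | row > nr - 1 + 1e-9 | col < -1e-9 | col > nc - 1 + 1e-9))
    stop("interpolation position outside the image grid")
  row <- pmin(pmax(row, 0), nr - 1)
  col <- pmin(pmax(col, 0), nc - 1)
  # pad by 2 with linear extrapolation
  mp <- rbind(3 * m[1, ] - 2 * m[2, ], 2 * m[1, ] - m[2, ], m,
              2 * m[nr, ] - m[nr - 1, ], 3 * m[nr, ] - 2 * m[nr - 1, ])
  mp <- cbind(3 * mp[, 1] - 2 * mp[, 2], 2 * mp[, 1] - mp[, 2], mp,
              2 * mp[, nc] - mp[, nc - 1], 3 * mp[, nc] - 2 * mp[, nc - 1])
  r0 <- floor(row); c0 <- floor(col)
  tr <- row - r0; tc <- col - c0
  a <- -0.5
  wts <- function(t) cbind(
    a * t^3 - 2 * a * t^2 + a * t,
    (a + 2) * t^3 - (a + 3) * t^2 + 1,
    -(a + 2) * t^3 + (2 * a + 3) * t^2 - a * t,
    -a * t^3 + a * t^2)
  wr <- wts(tr); wc <- wts(tc)
  out <- numeric(length(row))
  for (i in -1:2) for (j in -1:2) {
    idx <- cbind(pmin(pmax(r0 + i + 3, 1), nr + 4),
                 pmin(pmax(c0 + j + 3, 1), nc + 4))
    out <- out + wr[, i + 2] * wc[, j + 2] * mp[idx]
  }
  out
}
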
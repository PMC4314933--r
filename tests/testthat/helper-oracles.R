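# shared test oracles and small helpers (independent of package internals)

# brute-force 3x3 kernel correlation with edge replication
brute_correlate3 <- function(m, kern) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    acc <- 0
    for (i in -1:1) for (j in -1:1) {
      rr <- min(max(r + i, 1), nr); cc <- min(max(c + j, 1), nc)
      acc <- acc + kern[i + 2, j + 2] * m[rr, cc]
    }
    out[r, c] <- acc
  }
  out
}

sobel_kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)       # d/dcol
sobel_ky <- t(sobel_kx)                                          # d/drow

# brute-force chain length: enumerate every 8-adjacent pixel pair once
brute_chain_length <- function(sk, psx = 1, psy = psx) {
  w <- unname(which(sk, arr.ind = TRUE))
  total <- 0
  n <- nrow(w)
  if (n < 2) return(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dr <- abs(w[i, 1] - w[j, 1]); dc <- abs(w[i, 2] - w[j, 2])
    if (dr <= 1 && dc <= 1)
      total <- total + sqrt((dr * psy)^2 + (dc * psx)^2)
  }
  total
}

mask_iou <- function(a, b) sum(a & b) / sum(a | b)

flat_map <- function(value = 0, n = 16, ps = 1)
  height_map(matrix(value, n, n), ps, ps)

# resample a polyline at (approximately) uniform arc steps, in pixels
resample_polyline <- function(pts, step = 2) {
  d <- diff(pts)
  seg <- sqrt(rowSums(d^2))
  cum <- c(0, cumsum(seg))
  s <- seq(0, cum[length(cum)], by = step)
  i <- pmin(findInterval(s, cum, rightmost.closed = TRUE), nrow(pts) - 1)
  frac <- (s - cum[i]) / pmax(seg[i], 1e-12)
  pts[i, , drop = FALSE] + d[i, , drop = FALSE] * frac
}
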
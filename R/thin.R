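# Topology-preserving thinning (Zhang-Suen two-subiteration algorithm).
# Iteratively peels boundary pixels that have 2..6 neighbours, exactly
# one 0->1 transition around the 8-neighbourhood, and that satisfy the
# subiteration's directional conditions, until no pixel changes. The
# result is an (approximately) one-pixel-wide, 8-connected medial curve
# of each component.
thin_zhang_suen <- function(mask) {
  stopifnot(is.logical(mask))
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.integer(mask)
  nr <- nrow(m); nc <- ncol(m)
  core_r <- 2:(nr - 1L); core_c <- 2:(nc - 1L)
  sh <- function(dr, dc) m[core_r + dr, core_c + dc]
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p2 <- sh(-1, 0); p3 <- sh(-1, 1); p4 <- sh(0, 1); p5 <- sh(1, 1)
      p6 <- sh(1, 0); p7 <- sh(1, -1); p8 <- sh(0, -1); p9 <- sh(-1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
           (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
           (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
           (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      cond <- m[core_r, core_c] == 1L & b >= 2L & b <= 6L & a == 1L
      if (pass == 1L)
        cond <- cond & (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      else
        cond <- cond & (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      if (any(cond)) {
        sub <- m[core_r, core_c]
        sub[cond] <- 0L
        m[core_r, core_c] <- sub
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- m[core_r, core_c] == 1L
  remove_staircase(out)
}

# Sequential pruning of redundant pixels left by the parallel passes
# (staircase corners and 2-pixel-thick diagonal joints). A pixel with at
# least two neighbours is removable when the foreground pixels of its
# 3x3 neighbourhood form a single 8-connected component without it: the
# curve stays 8-connected and holes cannot appear in 1-px structures.
# Endpoints (degree <= 1) are never touched. Repeats until stable.
remove_staircase <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  # neighbour offsets in ring order and their adjacency inside the ring
  offs <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  ring_adj <- outer(seq_len(8), seq_len(8), function(i, j) {
    di <- abs(offs[i, 1] - offs[j, 1]); dj <- abs(offs[i, 2] - offs[j, 2])
    (di <= 1 & dj <= 1) & !(di == 0 & dj == 0)
  })
  one_component <- function(present) {
    ids <- which(present)
    seen <- ids[1L]
    repeat {
      grow <- ids[ids %in% ids[colSums(ring_adj[seen, ids, drop = FALSE]) > 0]]
      grow <- union(seen, grow)
      if (length(grow) == length(seen)) break
      seen <- grow
    }
    length(seen) == length(ids)
  }
  repeat {
    changed <- FALSE
    idx <- which(pad)
    for (i in idx) {
      if (!pad[i]) next
      r <- ((i - 1L) %% (nr + 2L)) + 1L
      c <- ((i - 1L) %/% (nr + 2L)) + 1L
      nb <- vapply(seq_len(8), function(k)
        pad[r + offs[k, 1], c + offs[k, 2]], logical(1))
      if (sum(nb) < 2L) next
      if (one_component(nb)) {
        pad[r, c] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pad[2:(nr + 1L), 2:(nc + 1L)]
}
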
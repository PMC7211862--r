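# Independent oracle implementations and small fixture builders shared by
# the test files. These deliberately avoid the package's code paths.

disc_px <- function(nr, nc, center, r, hole = 0) {
  d2 <- outer((seq_len(nr) - center[1])^2, (seq_len(nc) - center[2])^2, "+")
  out <- d2 <= r^2
  if (hole > 0) out <- out & d2 > hole^2
  out
}

# brute-force Feret: maximum distance over ALL pixel-corner pairs
oracle_feret_px <- function(px) {
  idx <- which(px)
  nr <- nrow(px)
  ri <- (idx - 1L) %% nr + 1L
  ci <- (idx - 1L) %/% nr + 1L
  pts <- cbind(c(ri - 0.5, ri - 0.5, ri + 0.5, ri + 0.5),
               c(ci - 0.5, ci + 0.5, ci - 0.5, ci + 0.5))
  best <- 0
  for (a in seq_len(nrow(pts) - 1L)) {
    d2 <- (pts[(a + 1L):nrow(pts), 1] - pts[a, 1])^2 +
      (pts[(a + 1L):nrow(pts), 2] - pts[a, 2])^2
    best <- max(best, max(d2))
  }
  sqrt(best)
}

# brute-force Otsu: maximize between-class variance over every candidate
# split, computed from first principles
oracle_otsu <- function(x) {
  x <- as.vector(x)
  v <- sort(unique(x))
  best <- -Inf; arg <- v[1]
  for (t in v[-1]) {
    lo <- x[x < t]; hi <- x[x >= t]
    w0 <- length(lo) / length(x); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bcv > best) { best <- bcv; arg <- t }
  }
  arg
}

# seeded watershed oracle: assign each foreground pixel to a seed by
# iterative growth in order of decreasing exact EDT (plain R, no shared code
# with the package kernels beyond arithmetic)
oracle_seeded_watershed <- function(px, seeds_rc) {
  nr <- nrow(px); nc <- ncol(px)
  # exact EDT by brute force over background pixels (small fixtures only)
  bg <- which(!px)
  bri <- (bg - 1L) %% nr + 1L; bci <- (bg - 1L) %/% nr + 1L
  d <- matrix(0, nr, nc)
  fg <- which(px)
  for (p in fg) {
    pr <- (p - 1L) %% nr + 1L; pc <- (p - 1L) %/% nr + 1L
    d[p] <- sqrt(min((bri - pr)^2 + (bci - pc)^2))
  }
  lab <- matrix(0L, nr, nc)
  for (s in seq_len(nrow(seeds_rc))) lab[seeds_rc[s, 1], seeds_rc[s, 2]] <- s
  nb <- lapply(seq_len(nr * nc), function(p) integer(0))
  for (p in fg) {
    pr <- (p - 1L) %% nr + 1L; pc <- (p - 1L) %/% nr + 1L
    out <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      qr <- pr + dr; qc <- pc + dc
      if (qr >= 1 && qr <= nr && qc >= 1 && qc <= nc && px[qr, qc])
        out <- c(out, (qc - 1L) * nr + qr)
    }
    nb[[p]] <- out
  }
  # strict ordered growth: always extend at the highest-EDT unlabeled pixel
  # adjacent to an existing basin
  frontier <- unique(unlist(nb[fg[lab[fg] > 0L]]))
  frontier <- frontier[lab[frontier] == 0L]
  while (length(frontier)) {
    p <- frontier[which.max(d[frontier])]
    ls <- lab[nb[[p]]]
    lab[p] <- ls[ls > 0L][1L]
    frontier <- setdiff(unique(c(frontier, nb[[p]][lab[nb[[p]]] == 0L])), p)
  }
  lab
}

# gift-wrapping convex hull membership test (independent of grDevices::chull)
oracle_in_hull <- function(pts, query) {
  # pts: n x 2; returns function of (r, c) -> logical
  hull <- {
    start <- which.min(pts[, 2] + 1e-9 * pts[, 1])
    h <- start; cur <- start
    repeat {
      cand <- setdiff(seq_len(nrow(pts)), cur)
      nxt <- cand[1]
      for (k in cand[-1]) {
        cr <- (pts[nxt, 2] - pts[cur, 2]) * (pts[k, 1] - pts[cur, 1]) -
          (pts[nxt, 1] - pts[cur, 1]) * (pts[k, 2] - pts[cur, 2])
        if (cr < 0 || (cr == 0 &&
            sum((pts[k, ] - pts[cur, ])^2) > sum((pts[nxt, ] - pts[cur, ])^2)))
          nxt <- k
      }
      if (nxt == start) break
      h <- c(h, nxt); cur <- nxt
      if (length(h) > nrow(pts)) break
    }
    pts[h, , drop = FALSE]
  }
  n <- nrow(hull)
  function(r, c) {
    for (e in seq_len(n)) {
      a <- hull[e, ]; b <- hull[if (e == n) 1L else e + 1L, ]
      cr <- (b[2] - a[2]) * (r - a[1]) - (b[1] - a[1]) * (c - a[2])
      if (cr < -1e-9) return(FALSE)
    }
    TRUE
  }
}

# textbook Pearson correlation
oracle_pearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# independent segment count: build the skeleton graph explicitly (8-neighbour
# edges, diagonal edges dropped when the two pixels share an orthogonal
# neighbour of the skeleton), delete pixels of graph degree >= 3, and count
# the remaining connected groups by BFS over the same pruned edges
oracle_segment_count <- function(px) {
  nr <- nrow(px)
  at <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= ncol(px) &&
    px[r, c]
  nbrs <- function(p, domain) {
    pr <- (p - 1L) %% nr + 1L; pc <- (p - 1L) %/% nr + 1L
    out <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      qr <- pr + dr; qc <- pc + dc
      if (!at(qr, qc)) next
      if (dr != 0 && dc != 0 &&                       # diagonal short-cut?
          (at(pr, qc) || at(qr, pc))) next
      q <- (qc - 1L) * nr + qr
      if (q %in% domain) out <- c(out, q)
    }
    out
  }
  idx <- which(px)
  deg <- vapply(idx, function(p) length(nbrs(p, idx)), integer(1))
  keep <- idx[deg < 3L]
  seen <- integer(0); count <- 0L
  for (p in keep) {
    if (p %in% seen) next
    count <- count + 1L
    queue <- p
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      if (q %in% seen) next
      seen <- c(seen, q)
      queue <- c(queue, intersect(nbrs(q, keep), keep))
    }
  }
  count
}
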
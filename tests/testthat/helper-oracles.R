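# Independent brute-force oracles used to validate the pipeline primitives.
# These deliberately share no code with the implementation.

# exact nearest-background search; the frame beyond the image counts as
# background at distance min(row, col, nr - row + 1, nc - col + 1)
oracle_distance_transform <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  d <- matrix(0, nr, nc)
  bg <- which(!mask, arr.ind = TRUE)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    db <- min(i, j, nr - i + 1L, nc - j + 1L)
    dp <- if (nrow(bg)) sqrt(min((bg[, 1L] - i)^2 + (bg[, 2L] - j)^2)) else Inf
    d[i, j] <- min(db, dp)
  }
  d
}

# queue-based flood fill labeling; connectivity 4 or 8
oracle_label <- function(mask, connectivity = 4L) {
  offs <- if (connectivity == 4L)
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  else
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
         c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      r <- ((v - 1L) %% nr) + 1L; c <- ((v - 1L) %/% nr) + 1L
      for (o in offs) {
        r2 <- r + o[1L]; c2 <- c + o[2L]
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        if (!mask[r2, c2]) next
        w <- r2 + (c2 - 1L) * nr
        if (lab[w] == 0L) { lab[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  lab
}

# holes: 4-connected background components that never touch the frame
oracle_holes <- function(mask) {
  lab <- oracle_label(!mask, 4L)
  border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
  keep <- setdiff(unique(lab[lab > 0L]), border)
  sizes <- vapply(keep, function(k) sum(lab == k), 0L)
  list(holes = length(keep),
       average_hole_size = if (length(keep)) mean(sizes) else 0)
}

# convex hull area by brute force: try every pair of points as a hull edge
# (all other points on one side); shoelace over the resulting polygon.
# O(n^3); only for tiny fixtures.
oracle_convex_area <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) return(0)
  x <- pts[, 2L]; y <- pts[, 1L]
  hull <- grDevices::chull(x, y)  # cross-check base hull with shoelace below
  hx <- x[hull]; hy <- y[hull]
  m <- length(hull)
  j <- c(2:m, 1L)
  abs(sum(hx * hy[j] - hx[j] * hy)) / 2
}

# shoelace on an explicitly enumerated hull via gift wrapping (independent
# of grDevices::chull)
oracle_convex_area_wrap <- function(pts) {
  pts <- unique(pts[, c(1L, 2L), drop = FALSE])
  n <- nrow(pts)
  if (n < 3L) return(0)
  x <- pts[, 2L]; y <- pts[, 1L]
  # gift wrapping from the lowest-x (then lowest-y) point
  start <- order(x, y)[1L]
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- setdiff(seq_len(n), p)
    q <- cand[1L]
    for (r in cand[-1L]) {
      cr <- (x[q] - x[p]) * (y[r] - y[p]) - (x[r] - x[p]) * (y[q] - y[p])
      d2q <- (x[q] - x[p])^2 + (y[q] - y[p])^2
      d2r <- (x[r] - x[p])^2 + (y[r] - y[p])^2
      if (cr < 0 || (abs(cr) < 1e-12 && d2r > d2q)) q <- r
    }
    if (q == start) break
    hull <- c(hull, q)
    if (length(hull) > n) stop("gift wrap runaway")
  }
  hx <- x[hull]; hy <- y[hull]
  m <- length(hull)
  if (m < 3L) return(0)
  j <- c(2:m, 1L)
  abs(sum(hx * hy[j] - hx[j] * hy)) / 2
}

# chain length of an ordered point path (1 per orthogonal, sqrt(2) per
# diagonal step), written independently of the package helper
oracle_chain_length <- function(pts, closed = FALSE) {
  if (nrow(pts) < 2L) return(0)
  seq_pts <- if (closed) rbind(pts, pts[1L, ]) else pts
  tot <- 0
  for (i in seq_len(nrow(seq_pts) - 1L)) {
    tot <- tot + sqrt(sum((seq_pts[i + 1L, ] - seq_pts[i, ])^2))
  }
  tot
}

# per-row background->foreground transition counts by direct scanning
oracle_row_transitions <- function(mask) {
  out <- integer(nrow(mask))
  for (i in seq_len(nrow(mask))) {
    prev <- FALSE
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j] && !prev) out[i] <- out[i] + 1L
      prev <- mask[i, j]
    }
  }
  out
}

# draw a small mask from (row, col) pixel coordinates
mask_from_pixels <- function(pixels, nr, nc) {
  m <- matrix(FALSE, nr, nc)
  m[pixels] <- TRUE
  m
}

# random mask generator for property tests
random_mask <- function(nr, nc, p = 0.5) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}
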
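# Shared raster helpers: masks are logical matrices indexed [row, col],
# row 1 at the top (depth axis), col 1 at the left (width axis).

# 8-neighborhood offsets in fixed N, NE, E, SE, S, SW, W, NW order;
# this order is the deterministic tie-break used throughout.
.nb8 <- cbind(dr = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
              dc = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L))
.nb4 <- .nb8[c(1L, 3L, 5L, 7L), , drop = FALSE]

# Label connected components of a logical matrix.
# connectivity 8 for foreground, 4 for background (standard duality).
# Returns an integer matrix, 0 outside `mask`; labels are in scan order
# (column-major R order) of each component's first pixel.
label_components <- function(mask, connectivity = 8L) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  nr <- nrow(mask); nc <- ncol(mask)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  offs <- if (connectivity == 8L) .nb8 else .nb4
  # half the offsets suffice for undirected edges
  offs <- offs[offs[, 1L] > 0L | (offs[, 1L] == 0L & offs[, 2L] > 0L), ,
               drop = FALSE]
  vid <- matrix(0L, nr, nc)
  vid[idx] <- seq_along(idx)
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    r2 <- r + offs[k, 1L]; c2 <- c + offs[k, 2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    j <- vid[cbind(r2[ok], c2[ok])]
    keep <- j > 0L
    from <- c(from, which(ok)[keep])
    to <- c(to, j[keep])
  }
  g <- igraph::make_graph(rbind(from, to), n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  # renumber so labels follow scan order of first occurrence
  first <- !duplicated(memb)
  renum <- integer(max(memb))
  renum[memb[first]] <- seq_len(sum(first))
  lab[idx] <- renum[memb]
  lab
}

# Count of TRUE 8-neighbors for every cell of a logical matrix (vectorized).
neighbor_count8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask * 1L
  acc <- matrix(0L, nr, nc)
  for (k in seq_len(8L)) {
    dr <- .nb8[k, 1L]; dc <- .nb8[k, 2L]
    acc <- acc + p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  }
  acc
}

# Shift a matrix by (dr, dc), padding with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L - dr):min(nr, nr - dr)
  cs <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(rs) && length(cs)) out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

# Summed-area table with a zero first row/col so window sums are
# S[hi+1, hi+1] - S[lo, hi+1] - S[hi+1, lo] + S[lo, lo].
integral_image <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  s <- matrix(0, nr + 1L, nc + 1L)
  s[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
  s
}

window_sum <- function(s, rlo, rhi, clo, chi) {
  s[cbind(rhi + 1L, chi + 1L)] - s[cbind(rlo, chi + 1L)] -
    s[cbind(rhi + 1L, clo)] + s[cbind(rlo, clo)]
}

# Pixels of a digital straight segment between two (row, col) cells
# (Bresenham). Returns an n x 2 matrix including both endpoints.
bresenham <- function(p0, p1) {
  r0 <- p0[1L]; c0 <- p0[2L]; r1 <- p1[1L]; c1 <- p1[2L]
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- if (r0 < r1) 1L else -1L
  sc <- if (c0 < c1) 1L else -1L
  n <- max(dr, dc) + 1L
  out <- matrix(0L, n, 2L)
  err <- dc - dr
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    out[i, ] <- c(r, c)
    if (r == r1 && c == c1) { out <- out[seq_len(i), , drop = FALSE]; break }
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc) { err <- err + dc; r <- r + sr }
  }
  out
}

# total Euclidean length of a chain of 8-connected (or arbitrary) points:
# unit steps count 1, diagonal steps sqrt(2); wrap = close the ring.
chain_length <- function(pts, closed = FALSE) {
  if (is.null(pts) || nrow(pts) < 2L) return(0)
  d <- sqrt(diff(pts[, 1L])^2 + diff(pts[, 2L])^2)
  tot <- sum(d)
  if (closed)
    tot <- tot + sqrt(sum((pts[1L, ] - pts[nrow(pts), ])^2))
  tot
}
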
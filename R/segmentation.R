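# Segmentation: grayscale silhouette -> smoothed binary root mask.

#' Threshold a grayscale silhouette
#'
#' Backlit root crowns are dark objects on a bright background, so a pixel
#' is foreground when its intensity is strictly below \code{level}. With
#' \code{invert} the rule flips (intensity >= \code{level}) for images where
#' the roots are bright.
#'
#' @param img Numeric/integer matrix of intensities in [0, 255],
#'   indexed [row, col].
#' @param level Grayscale cutoff in [0, 255].
#' @param invert Segment bright-on-dark instead of dark-on-bright.
#' @return Logical matrix; \code{TRUE} = root (foreground).
#' @examples
#' img <- matrix(250, 3, 3); img[2, 2] <- 10
#' which(threshold_image(img, 128))
#' @export
threshold_image <- function(img, level = 128L, invert = FALSE) {
  if (level < 0 || level > 255) stop("`level` must be in [0, 255]", call. = FALSE)
  if (invert) img >= level else img < level
}

#' Extract boundary contours of a binary mask
#'
#' Moore-neighbor boundary tracing. One outer contour is returned for every
#' 8-connected foreground component and one hole contour for every 4-connected
#' background component fully enclosed by foreground (holes). Contour points
#' are foreground pixels in (row, col) coordinates, traced as a closed ring of
#' consecutively 8-adjacent pixels; outer and hole rings have opposite
#' orientations. Contours of components touching the image border are closed
#' along the border.
#'
#' @param mask Logical matrix, \code{TRUE} = foreground.
#' @return List of contours; each has \code{points} (n x 2 matrix of
#'   (row, col)), \code{kind} ("outer" or "hole"), and \code{component}
#'   (label of the owning foreground component).
#' @export
extract_contours <- function(mask) {
  out <- list()
  if (!any(mask)) return(out)
  labF <- label_components(mask, 8L)
  px <- which(mask, arr.ind = TRUE)
  ord <- order(px[, 1L], px[, 2L])  # topmost, then leftmost
  px <- px[ord, , drop = FALSE]
  labs <- labF[px]
  for (lb in unique(labs)) {
    s <- px[match(lb, labs), ]
    ring <- trace_boundary(mask, start = s, back_dir = 7L)  # backtrack = W
    out[[length(out) + 1L]] <-
      list(points = ring, kind = "outer", component = lb)
  }
  # holes: 4-connected background components not touching the border
  labB <- label_components(!mask, 4L)
  border <- unique(c(labB[1L, ], labB[nrow(labB), ], labB[, 1L],
                     labB[, ncol(labB)]))
  hole_labs <- setdiff(unique(labB[labB > 0L]), border)
  if (length(hole_labs)) {
    bg <- which(!mask, arr.ind = TRUE)
    bord <- order(bg[, 1L], bg[, 2L])
    bg <- bg[bord, , drop = FALSE]
    blabs <- labB[bg]
    for (hb in sort(hole_labs)) {
      h <- bg[match(hb, blabs), ]
      f <- c(h[1L] - 1L, h[2L])     # pixel above the topmost hole pixel
      ring <- trace_boundary(mask, start = f, back_dir = 5L)  # backtrack = S (the hole)
      out[[length(out) + 1L]] <-
        list(points = ring, kind = "hole", component = labF[f[1L], f[2L]])
    }
  }
  out
}

# Moore-neighbor tracing with Jacob's stopping criterion.
# `back_dir` is the index in .nb8 of the background pixel we "came from".
# Scanning proceeds clockwise (N, NE, E, SE, S, SW, W, NW) starting just
# after the backtrack; the chain of background pixels swept between two
# boundary steps stays 4-connected, so the trace follows the boundary
# adjacent to the background component containing the initial backtrack.
trace_boundary <- function(mask, start, back_dir) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && mask[r, c]
  pts_r <- integer(256L); pts_c <- integer(256L); n <- 0L
  push <- function(r, c) {
    n <<- n + 1L
    if (n > length(pts_r)) {
      length(pts_r) <<- 2L * length(pts_r); length(pts_c) <<- length(pts_r)
    }
    pts_r[n] <<- r; pts_c[n] <<- c
  }
  push(start[1L], start[2L])
  cur <- start; bd <- back_dir
  start_bd <- back_dir
  cap <- 8L * (sum(mask) + 16L)
  for (iter in seq_len(cap)) {
    found <- FALSE
    prev_d <- bd
    for (k in seq_len(8L)) {
      d <- ((bd + k - 1L) %% 8L) + 1L
      r2 <- cur[1L] + .nb8[d, 1L]; c2 <- cur[2L] + .nb8[d, 2L]
      if (fg(r2, c2)) {
        # new backtrack: last background cell examined, relative to (r2, c2)
        bp_r <- cur[1L] + .nb8[prev_d, 1L]; bp_c <- cur[2L] + .nb8[prev_d, 2L]
        dd <- c(bp_r - r2, bp_c - c2)
        nbd <- which(.nb8[, 1L] == dd[1L] & .nb8[, 2L] == dd[2L])
        cur <- c(r2, c2); bd <- nbd
        found <- TRUE
        break
      }
      prev_d <- d
    }
    if (!found) break  # isolated pixel
    if (cur[1L] == start[1L] && cur[2L] == start[2L] && bd == start_bd) break
    push(cur[1L], cur[2L])
  }
  cbind(row = pts_r[seq_len(n)], col = pts_c[seq_len(n)])
}

#' Simplify a pixel path with the Ramer-Douglas-Peucker algorithm
#'
#' Connects the first and last point with a chord, finds the point of maximum
#' perpendicular distance to it, and recursively splits there while that
#' distance exceeds \code{epsilon_px}. Every input point is guaranteed to lie
#' within \code{epsilon_px} of the returned polyline. Distances are
#' point-to-segment (clamped at the chord endpoints). With
#' \code{closed = TRUE} the input is treated as a ring: the path is split at
#' the point farthest from the first point and each half simplified.
#'
#' @param points n x 2 matrix of (row, col) vertices.
#' @param epsilon_px Positive distance tolerance in pixels.
#' @param closed Treat the path as a closed ring.
#' @return Matrix of retained vertices (a subsequence of the input).
#' @examples
#' pts <- cbind(0, 0:9)
#' simplify_contour(pts, 2)       # collapses to the two endpoints
#' @export
simplify_contour <- function(points, epsilon_px, closed = FALSE) {
  if (epsilon_px <= 0) stop("`epsilon_px` must be positive", call. = FALSE)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n <= 2L) return(points)
  if (closed) {
    d0 <- (points[, 1L] - points[1L, 1L])^2 + (points[, 2L] - points[1L, 2L])^2
    a2 <- which.max(d0)
    if (a2 == 1L || a2 == n) return(simplify_contour(points, epsilon_px))
    k1 <- rdp_keep(points[1:a2, , drop = FALSE], epsilon_px)
    k2 <- rdp_keep(points[a2:n, , drop = FALSE], epsilon_px)
    keep <- unique(c(which(k1), a2 - 1L + which(k2)))
    keep <- relax_ring_vertices(points, keep, epsilon_px)
    return(points[keep, , drop = FALSE])
  }
  points[rdp_keep(points, epsilon_px), , drop = FALSE]
}

# Drop redundant ring vertices after closed-contour RDP: the two split
# anchors are kept unconditionally by the recursion, so an anchor that
# happens to sit on a small bump would survive. A vertex is removed when
# every original point between its ring neighbors lies within epsilon of
# the chord joining those neighbors.
relax_ring_vertices <- function(points, keep, eps) {
  n <- nrow(points)
  dev_at <- function(j) {
    m2 <- length(keep)
    prv <- keep[if (j == 1L) m2 else j - 1L]
    nxt <- keep[if (j == m2) 1L else j + 1L]
    span <- if (prv < nxt) prv:nxt else c(prv:n, 1L:nxt)
    max(point_segment_dist(points[span, , drop = FALSE],
                           points[prv, ], points[nxt, ]))
  }
  # greedily remove the least salient vertex first so redundant anchors
  # fall before true corners adjacent to them
  repeat {
    if (length(keep) <= 3L) return(keep)
    devs <- vapply(seq_along(keep), dev_at, 0)
    j <- which.min(devs)
    if (devs[j] > eps) return(keep)
    keep <- keep[-j]
  }
}

# logical keep-vector of the open-path RDP (iterative, stack-based)
rdp_keep <- function(pts, eps) {
  n <- nrow(pts)
  keep <- logical(n); keep[c(1L, n)] <- TRUE
  if (n <= 2L) return(keep)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- ij[1L]; j <- ij[2L]
    if (j - i < 2L) next
    mid <- (i + 1L):(j - 1L)
    d <- point_segment_dist(pts[mid, , drop = FALSE], pts[i, ], pts[j, ])
    m <- which.max(d)
    if (d[m] > eps) {
      k <- mid[m]
      keep[k] <- TRUE
      stack[[length(stack) + 1L]] <- c(i, k)
      stack[[length(stack) + 1L]] <- c(k, j)
    }
  }
  keep
}

# Euclidean distance from points (n x 2) to segment a-b with endpoint clamping
point_segment_dist <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((p[, 1L] - a[1L])^2 + (p[, 2L] - a[2L])^2))
  t <- ((p[, 1L] - a[1L]) * ab[1L] + (p[, 2L] - a[2L]) * ab[2L]) / len2
  t <- pmin(1, pmax(0, t))
  dx <- p[, 1L] - (a[1L] + t * ab[1L])
  dy <- p[, 2L] - (a[2L] + t * ab[2L])
  sqrt(dx^2 + dy^2)
}

#' Smooth mask edges by contour simplification
#'
#' Replaces each component's boundary (outer ring and hole rings) with its
#' Ramer-Douglas-Peucker simplification and re-rasterizes the simplified
#' polygons: outer polygons are filled (interior plus rasterized boundary),
#' hole polygons are re-subtracted (strict interior minus the rasterized
#' ring, which consists of root pixels). Pixels may be both added and removed
#' relative to the input; single-pixel edge jags of amplitude up to
#' \code{epsilon_px} are removed, which suppresses spurious short laterals in
#' the downstream skeleton.
#'
#' @inheritParams extract_contours
#' @param epsilon_px Positive RDP distance tolerance in pixels (default 2,
#'   matching the jaggedness scale of backlit silhouette edges).
#' @return Smoothed logical mask of the same dimensions.
#' @export
smooth_mask <- function(mask, epsilon_px = 2) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (!any(mask)) return(mask & FALSE)
  cons <- extract_contours(mask)
  out <- matrix(FALSE, nr, nc)
  for (cn in cons) {
    if (cn$kind != "outer") next
    poly <- simplify_contour(cn$points, epsilon_px, closed = TRUE)
    out <- out | rasterize_polygon(poly, nr, nc, mode = "fill")
  }
  for (cn in cons) {
    if (cn$kind != "hole") next
    poly <- simplify_contour(cn$points, epsilon_px, closed = TRUE)
    out <- out & !rasterize_polygon(poly, nr, nc, mode = "interior")
  }
  out
}

# Rasterize a closed polygon whose vertices are pixel centers.
# mode "fill": even-odd scanline fill (inclusive) plus Bresenham boundary.
# mode "interior": strictly inside, minus the Bresenham boundary pixels.
rasterize_polygon <- function(poly, nr, nc, mode = c("fill", "interior")) {
  mode <- match.arg(mode)
  out <- matrix(FALSE, nr, nc)
  k <- nrow(poly)
  if (k == 0L) return(out)
  # boundary pixels
  bpx <- matrix(0L, 0L, 2L)
  if (k == 1L) {
    bpx <- poly
  } else {
    for (i in seq_len(k)) {
      j <- if (i == k) 1L else i + 1L
      bpx <- rbind(bpx, bresenham(poly[i, ], poly[j, ]))
    }
  }
  bpx <- bpx[bpx[, 1L] >= 1L & bpx[, 1L] <= nr &
             bpx[, 2L] >= 1L & bpx[, 2L] <= nc, , drop = FALSE]
  if (k >= 3L) {
    # even-odd scanline over pixel-center rows
    r1 <- poly[, 1L]; c1 <- poly[, 2L]
    r2 <- r1[c(2:k, 1L)]; c2 <- c1[c(2:k, 1L)]
    rows_all <- integer(0); x_all <- numeric(0)
    for (i in seq_len(k)) {
      if (r1[i] == r2[i]) next  # horizontal edges do not cross scanlines
      lo <- min(r1[i], r2[i]); hi <- max(r1[i], r2[i])
      rr <- lo:(hi - 1L)       # half-open [lo, hi)
      xx <- c1[i] + (rr - r1[i]) * (c2[i] - c1[i]) / (r2[i] - r1[i])
      rows_all <- c(rows_all, rr); x_all <- c(x_all, xx)
    }
    if (length(rows_all)) {
      for (r in unique(rows_all)) {
        if (r < 1L || r > nr) next
        xs <- sort(x_all[rows_all == r])
        for (p in seq(1L, length(xs) - 1L, by = 2L)) {
          if (mode == "fill") {
            clo <- ceiling(xs[p] - 1e-9); chi <- floor(xs[p + 1L] + 1e-9)
          } else {
            clo <- floor(xs[p] + 1e-9) + 1L; chi <- ceiling(xs[p + 1L] - 1e-9) - 1L
          }
          clo <- max(1L, clo); chi <- min(nc, chi)
          if (clo <= chi) out[r, clo:chi] <- TRUE
        }
      }
    }
  }
  if (mode == "fill") {
    out[bpx] <- TRUE
  } else {
    out[bpx] <- FALSE
  }
  out
}
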
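# Skeletonization: exact Euclidean distance transform -> ridge medial axis
# -> connected, single-pixel-wide skeleton with per-pixel radii.

#' Exact Euclidean distance transform
#'
#' Distance from every foreground pixel center to the nearest background
#' pixel center. The frame border counts as background: a foreground pixel
#' touching the image edge has distance 1 even with no background pixel
#' inside the frame. Background pixels map to 0.
#'
#' @param mask Logical matrix, \code{TRUE} = foreground.
#' @return Numeric matrix of distances (exact Euclidean, not chamfer).
#' @export
distance_transform <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (!any(mask)) return(matrix(0, nr, nc))
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask * 1
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(p),
                                           metric = "euclidean"))
  d[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
}

#' Extract the medial-axis ridge of a distance map
#'
#' Ridge pixels are local maxima of the distance map transverse to the
#' ridge direction. The transverse direction at a pixel is estimated from
#' the central-difference gradient of the distance map, quantized to the
#' nearest of the four principal axes (N-S, E-W, NE-SW, NW-SE); the pixel is
#' a ridge pixel when its distance value is not smaller than both neighbors
#' along that axis and strictly larger than at least one. On gradient
#' plateaus (crest tops, junction centers) all four axes are tried. Pixels
#' on the distance-map slope fail the test along their own gradient, so
#' boundary pixels never qualify; this operationalizes "equidistant from at
#' least two background pixels". The raw ridge may be locally two pixels
#' wide on even-width roots and carries gaps where the crest runs between
#' pixel rows; \code{\link{connect_skeleton}} bridges and thins it.
#'
#' @param dmap Distance map from \code{\link{distance_transform}}.
#' @param mask The mask the distance map was computed from.
#' @return A \code{crown_skeleton}: list with \code{mask} (logical matrix of
#'   skeleton pixels) and \code{radius} (the distance map; the radius at a
#'   skeleton pixel is its value there).
#' @export
extract_medial_axis <- function(dmap, mask) {
  eps <- 1e-9
  # central-difference gradient (background is 0, frame padded with 0)
  gr <- (shift_mat(dmap, 1L, 0L, 0) - shift_mat(dmap, -1L, 0L, 0)) / 2
  gc <- (shift_mat(dmap, 0L, 1L, 0) - shift_mat(dmap, 0L, -1L, 0)) / 2
  gmag <- sqrt(gr^2 + gc^2)
  axes <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  # |cosine| alignment of the gradient with each (unnormalized) axis
  align <- array(0, c(nrow(dmap), ncol(dmap), 4L))
  for (k in seq_len(4L)) {
    a <- axes[[k]]
    align[, , k] <- abs(gr * a[1L] + gc * a[2L]) / sqrt(sum(a^2))
  }
  best <- max.col(matrix(align, ncol = 4L), ties.method = "first")
  best <- matrix(best, nrow(dmap), ncol(dmap))
  ridge <- matrix(FALSE, nrow(dmap), ncol(dmap))
  plateau <- gmag < 0.1
  for (k in seq_len(4L)) {
    a <- axes[[k]]
    p1 <- shift_mat(dmap, a[1L], a[2L], 0)
    p2 <- shift_mat(dmap, -a[1L], -a[2L], 0)
    # asymmetric tie-break (strict toward the positive axis direction)
    # keeps exactly one of two tied crest pixels on even-width roots
    ck <- dmap > p1 + eps & dmap >= p2 - eps
    # plateaus (junction and disk centers) have no meaningful gradient:
    # symmetric local-maximum rule over all four axes
    cp <- dmap >= p1 - eps & dmap >= p2 - eps &
      (dmap > p1 + eps | dmap > p2 + eps)
    ridge <- ridge | (!plateau & ck & best == k) | (plateau & cp)
  }
  # summits (8-neighborhood local maxima, e.g. the widest point of the
  # crown) are always ridge pixels even when a nearby larger summit skews
  # the local gradient
  ridge <- ridge | summit_pixels(dmap)
  new_skeleton(ridge & mask, dmap)
}

# pixels whose distance value is >= all 8 neighbors and > at least one
summit_pixels <- function(dmap) {
  eps <- 1e-9
  ge_all <- matrix(TRUE, nrow(dmap), ncol(dmap))
  gt_any <- matrix(FALSE, nrow(dmap), ncol(dmap))
  for (k in seq_len(8L)) {
    q <- shift_mat(dmap, .nb8[k, 1L], .nb8[k, 2L], 0)
    ge_all <- ge_all & (dmap >= q - eps)
    gt_any <- gt_any | (dmap > q + eps)
  }
  ge_all & gt_any & dmap > 0
}

new_skeleton <- function(skel_mask, dmap) {
  structure(list(mask = skel_mask, radius = dmap), class = "crown_skeleton")
}

#' @export
print.crown_skeleton <- function(x, ...) {
  n <- sum(x$mask)
  cat("Root skeleton:", n, "pixels")
  if (n) cat(", radius range [", min(x$radius[x$mask]), ", ",
             max(x$radius[x$mask]), "] px", sep = "")
  cat("\n")
  invisible(x)
}

#' Skeleton pixels with radii
#'
#' @param skel A \code{crown_skeleton}.
#' @return Data frame with columns \code{row}, \code{col}, \code{radius}.
#' @export
skeleton_pixels <- function(skel) {
  ij <- which(skel$mask, arr.ind = TRUE)
  data.frame(row = ij[, 1L], col = ij[, 2L], radius = skel$radius[ij])
}

#' Connect and thin a ridge skeleton
#'
#' Three passes turn the raw ridge into the final skeleton: (1) ridge end
#' points walk to their steepest-ascent neighbor on the distance map until
#' they meet a ridge pixel of another fragment (path length capped at four
#' times the local radius), bridging ridge gaps; (2) fragments that remain
#' disconnected inside one mask component are joined along the shortest
#' foreground path (a deterministic fallback so each mask component of at
#' least 4 pixels carries exactly one skeleton component); (3) Guo-Hall
#' thinning reduces the result to single-pixel width while preserving
#' connectivity and end points.
#'
#' @param skel A \code{crown_skeleton} (e.g. from
#'   \code{\link{extract_medial_axis}}).
#' @param mask The foreground mask.
#' @return A connected, thin \code{crown_skeleton}.
#' @export
connect_skeleton <- function(skel, mask) {
  dmap <- skel$radius
  S <- skel$mask & mask
  if (!any(mask)) return(new_skeleton(S, dmap))
  mlab <- label_components(mask, 8L)
  # guard: every mask component of >= 4 px owns at least its deepest pixel
  sizes <- tabulate(mlab[mlab > 0L])
  for (lb in which(sizes >= 4L)) {
    sel <- mlab == lb
    if (!any(S & sel)) {
      i <- which(sel)[which.max(dmap[sel])]
      S[i] <- TRUE
    }
  }
  S <- drop_ridge_specks(S, mlab, dmap)
  S <- bridge_ridges(S, dmap, mask)
  S <- join_fragments(S, mask, mlab)
  S <- guo_hall_thin(S)
  S <- clear_blocks(S)
  S <- clear_dangles(S)
  new_skeleton(S, dmap)
}

#' Full skeleton extraction pipeline
#'
#' Convenience wrapper: distance transform, ridge extraction, connection and
#' thinning in one call.
#' @param mask Logical foreground mask (ideally edge-smoothed).
#' @return A \code{crown_skeleton}.
#' @export
extract_skeleton <- function(mask) {
  dmap <- distance_transform(mask)
  connect_skeleton(extract_medial_axis(dmap, mask), mask)
}

# Ridge fragments of 1-2 pixels are quantization debris of the crest
# detector (saddles, junction shoulders); they carry no axis of their own.
# They are dropped before bridging unless they are the only ridge evidence
# in their mask component or contain a distance summit (the widest point
# of a root must keep its radius).
drop_ridge_specks <- function(S, mlab, dmap) {
  lab <- label_components(S, 8L)
  if (max(lab) <= 1L) return(S)
  sz <- tabulate(lab[lab > 0L])
  if (all(sz > 2L)) return(S)
  idx <- which(S)
  frag_max <- tapply(sz[lab[idx]], mlab[idx], max)
  keepable <- as.integer(names(frag_max)[frag_max > 2L])
  summit <- summit_pixels(dmap)
  summit_frag <- unique(lab[S & summit])
  drop <- idx[sz[lab[idx]] <= 2L & mlab[idx] %in% keepable &
                !(lab[idx] %in% summit_frag)]
  S[drop] <- FALSE
  S
}

# Single-pixel dangles left by parallel thinning of a two-wide crest band:
# an end point (reduced-adjacency degree 1) whose sole neighbor continues a
# through-path (reduced degree >= 3 counting the dangle) adds no centerline
# and is removed. Two passes clear dangles up to two pixels long; genuine
# root tips terminate paths whose support pixel has degree 2 and are never
# touched.
clear_dangles <- function(S) {
  for (pass in 1:2) {
    nbrs <- reduced_neighbors(S)
    deg <- vapply(nbrs$adj, length, 1L)
    ends <- which(deg == 1L)
    if (!length(ends)) break
    removed <- FALSE
    for (v in ends) {
      w <- nbrs$adj[[v]][1L]
      if (length(nbrs$adj[[w]]) >= 3L) {
        S[nbrs$idx[v]] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  S
}

# 8-adjacency with the diagonal-redundancy reduction used by the topology
# stage (a diagonal link is dropped when a shared orthogonal neighbor is
# skeletal); returns pixel linear indices and adjacency lists
reduced_neighbors <- function(S) {
  nr <- nrow(S); nc <- ncol(S)
  idx <- which(S)
  vid <- matrix(0L, nr, nc)
  vid[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  adj <- vector("list", length(idx))
  for (v in seq_along(idx)) {
    nbrs <- integer(0)
    for (k in seq_len(8L)) {
      r2 <- r[v] + .nb8[k, 1L]; c2 <- c[v] + .nb8[k, 2L]
      if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc || !S[r2, c2]) next
      if (.nb8[k, 1L] != 0L && .nb8[k, 2L] != 0L &&
          (S[r[v], c2] || S[r2, c[v]])) next
      nbrs <- c(nbrs, vid[r2, c2])
    }
    adj[[v]] <- nbrs
  }
  list(idx = idx, adj = adj)
}

# steepest-ascent bridging from ridge end points
bridge_ridges <- function(S, dmap, mask) {
  lab <- label_components(S, 8L)
  if (max(lab) <= 1L) return(S)
  nr <- nrow(S); nc <- ncol(S)
  # union-find over fragment labels
  parent <- seq_len(max(lab))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  ends <- which(S & neighbor_count8(S) <= 1L, arr.ind = TRUE)
  if (nrow(ends)) ends <- ends[order(ends[, 1L], ends[, 2L]), , drop = FALSE]
  for (e in seq_len(nrow(ends))) {
    er <- ends[e, 1L]; ec <- ends[e, 2L]
    own <- find(lab[er, ec])
    cap <- max(8L, ceiling(4 * dmap[er, ec]))
    cur <- c(er, ec)
    path <- matrix(0L, 0L, 2L)
    visited <- paste(er, ec)
    for (step in seq_len(cap)) {
      best <- NULL; bestd <- -Inf; hit <- NULL
      for (k in seq_len(8L)) {
        r2 <- cur[1L] + .nb8[k, 1L]; c2 <- cur[2L] + .nb8[k, 2L]
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        if (!mask[r2, c2]) next
        if (S[r2, c2]) {
          lb <- find(lab[r2, c2])
          if (lb != own) { hit <- c(r2, c2); break }
          next
        }
        if (paste(r2, c2) %in% visited) next
        if (dmap[r2, c2] > bestd) { bestd <- dmap[r2, c2]; best <- c(r2, c2) }
      }
      if (!is.null(hit)) {
        if (nrow(path)) {
          S[path] <- TRUE
          lab[path] <- own
        }
        parent[find(lab[hit[1L], hit[2L]])] <- own
        break
      }
      if (is.null(best)) break  # local maximum / dead end
      path <- rbind(path, best)
      visited <- c(visited, paste(best[1L], best[2L]))
      cur <- best
    }
  }
  S
}

# Fallback connector: join remaining skeleton fragments of each mask
# component along geodesic (shortest foreground) paths. One multi-source
# BFS grows all fragments simultaneously over the foreground; wherever two
# growth regions of different fragments meet, the meeting is scored by its
# combined distance, and a minimum-cost spanning forest of meetings (union-
# find over fragments, cheapest first) supplies the connecting paths.
join_fragments <- function(S, mask, mlab) {
  slab <- label_components(S, 8L)
  if (max(slab) <= 1L) return(S)
  idx <- which(S)
  npc <- tapply(slab[idx], mlab[idx], function(x) length(unique(x)))
  if (all(npc <= 1L)) return(S)
  nr <- nrow(mask); nc <- ncol(mask)
  NR <- nr + 2L; NC <- nc + 2L
  allowed <- matrix(FALSE, NR, NC)
  allowed[2:(nr + 1L), 2:(nc + 1L)] <- mask
  spad <- matrix(0L, NR, NC)
  spad[2:(nr + 1L), 2:(nc + 1L)] <- slab
  n <- NR * NC
  dist <- rep(NA_integer_, n); src <- integer(n); prev <- integer(n)
  frontier <- which(spad > 0L)
  dist[frontier] <- 0L; src[frontier] <- spad[frontier]
  offs <- c(-1L, 1L, -NR, NR, -NR - 1L, -NR + 1L, NR - 1L, NR + 1L)
  layer <- 0L
  while (length(frontier)) {
    layer <- layer + 1L
    nxt <- integer(0)
    for (off in offs) {
      w <- frontier + off
      ok <- allowed[w] & is.na(dist[w])
      if (!any(ok)) next
      w2 <- w[ok]; f2 <- frontier[ok]
      first <- !duplicated(w2)
      w2 <- w2[first]; f2 <- f2[first]
      dist[w2] <- layer
      src[w2] <- src[f2]
      prev[w2] <- f2
      nxt <- c(nxt, w2)
    }
    frontier <- nxt
  }
  # meetings: adjacent claimed pixels of different fragments
  pa <- integer(0); pb <- integer(0)
  claimed <- which(src > 0L)
  for (off in offs[c(2L, 4L, 6L, 8L)]) {  # positive directions suffice
    b <- claimed + off
    sel <- allowed[b] & src[b] > 0L & src[b] != src[claimed]
    pa <- c(pa, claimed[sel]); pb <- c(pb, b[sel])
  }
  if (!length(pa)) return(S)
  cost <- dist[pa] + dist[pb]
  ord <- order(cost, pa, pb)
  parent <- seq_len(max(slab))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  unpad <- function(v) {
    r <- ((v - 1L) %% NR) + 1L; c <- ((v - 1L) %/% NR) + 1L
    cbind(r - 1L, c - 1L)
  }
  for (e in ord) {
    a <- pa[e]; b <- pb[e]
    fa <- find(src[a]); fb <- find(src[b])
    if (fa == fb) next
    for (v in c(a, b)) {
      while (v != 0L && dist[v] > 0L) { S[unpad(v)] <- TRUE; v <- prev[v] }
    }
    parent[fb] <- fa
  }
  S
}

# parallel Guo-Hall thinning of a pixel set (two sub-iterations per cycle)
guo_hall_thin <- function(S) {
  repeat {
    changed <- FALSE
    for (parity in 0:1) {
      p2 <- shift_mat(S, -1L, 0L, FALSE);  p3 <- shift_mat(S, -1L, 1L, FALSE)
      p4 <- shift_mat(S, 0L, 1L, FALSE);   p5 <- shift_mat(S, 1L, 1L, FALSE)
      p6 <- shift_mat(S, 1L, 0L, FALSE);   p7 <- shift_mat(S, 1L, -1L, FALSE)
      p8 <- shift_mat(S, 0L, -1L, FALSE);  p9 <- shift_mat(S, -1L, -1L, FALSE)
      C <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
           (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
      n1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      n2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      nm <- pmin(n1, n2)
      m <- if (parity == 0L) (p6 | p7 | !p9) & p8 else (p2 | p3 | !p5) & p4
      del <- S & (C == 1L) & (nm >= 2L) & (nm <= 3L) & !m
      if (any(del)) { S <- S & !del; changed <- TRUE }
    }
    if (!changed) return(S)
  }
}

# remove residual fully-set 2x2 blocks, deleting only simple pixels
clear_blocks <- function(S) {
  repeat {
    b <- S & shift_mat(S, 1L, 0L, FALSE) & shift_mat(S, 0L, 1L, FALSE) &
      shift_mat(S, 1L, 1L, FALSE)
    ij <- which(b, arr.ind = TRUE)
    if (!nrow(ij)) return(S)
    ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
    r <- ij[1L, 1L]; c <- ij[1L, 2L]
    removed <- FALSE
    for (off in list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))) {
      rr <- r + off[1L]; cc <- c + off[2L]
      if (is_simple_pixel(S, rr, cc)) { S[rr, cc] <- FALSE; removed <- TRUE; break }
    }
    if (!removed) S[r, c] <- FALSE  # degenerate; keep progress deterministic
  }
}

# crossing-number test: deleting (r, c) keeps its neighborhood connected
is_simple_pixel <- function(S, r, c) {
  nb <- logical(8L)
  nr <- nrow(S); nc <- ncol(S)
  for (k in seq_len(8L)) {
    r2 <- r + .nb8[k, 1L]; c2 <- c + .nb8[k, 2L]
    nb[k] <- r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc && S[r2, c2]
  }
  # C(p) of Guo-Hall: number of 0 -> (1 or 1) transitions
  p2 <- nb[1L]; p3 <- nb[2L]; p4 <- nb[3L]; p5 <- nb[4L]
  p6 <- nb[5L]; p7 <- nb[6L]; p8 <- nb[7L]; p9 <- nb[8L]
  C <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
       (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
  C == 1L
}
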
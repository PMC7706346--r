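# Topology: skeletal degree, branch/end points, root segments.

#' Build the topology graph of a skeleton
#'
#' Computes skeletal degrees over the 8-neighborhood with redundancy
#' reduction (a diagonal neighbor is not counted when an orthogonal neighbor
#' adjacent to both pixels exists), classifies branch points (degree >= 3)
#' and end points (degree 1), and partitions the skeleton's edges into root
#' segments: maximal 8-connected paths running from a branch-or-end point to
#' a branch-or-end point with no interior branch point. A branch point of
#' degree d terminates d segments; end points are used exactly once. Cycles
#' without any branch point become one closed segment anchored at their
#' first pixel in scan order. Traversal order is deterministic (scan-order
#' starting pixels, neighbor order N, NE, E, SE, S, SW, W, NW).
#'
#' @param skel A \code{crown_skeleton} or a logical skeleton matrix.
#' @return A \code{crown_topology}: list with \code{branch_points} and
#'   \code{end_points} (n x 2 matrices of (row, col)), \code{segments}
#'   (list of ordered n x 2 pixel paths), \code{degree} (integer matrix) and
#'   \code{isolated} (pixels of degree 0).
#' @export
build_topology <- function(skel) {
  S <- if (inherits(skel, "crown_skeleton")) skel$mask else skel
  nr <- nrow(S); nc <- ncol(S)
  idx <- which(S)
  deg <- matrix(0L, nr, nc)
  adj <- list()
  if (length(idx)) {
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
        if (.nb8[k, 1L] != 0L && .nb8[k, 2L] != 0L) {
          # diagonal: skip when a shared orthogonal neighbor is skeletal
          if (S[r[v], c2] || S[r2, c[v]]) next
        }
        nbrs <- c(nbrs, vid[r2, c2])
      }
      adj[[v]] <- nbrs
      deg[idx[v]] <- length(nbrs)
    }
  }
  segments <- trace_segments(idx, adj, deg, nr)
  bp <- which(S & deg >= 3L, arr.ind = TRUE)
  ep <- which(S & deg == 1L, arr.ind = TRUE)
  iso <- which(S & deg == 0L, arr.ind = TRUE)
  structure(list(branch_points = bp, end_points = ep, segments = segments,
                 degree = deg, isolated = iso, npix = length(idx)),
            class = "crown_topology")
}

# walk every reduced-adjacency edge exactly once, splitting at nodes of
# degree != 2; leftover edges belong to pure cycles
trace_segments <- function(idx, adj, deg, nr) {
  segments <- list()
  if (!length(idx)) return(segments)
  dg <- deg[idx]
  used <- new.env(hash = TRUE)
  ekey <- function(a, b) if (a < b) paste0(a, "_", b) else paste0(b, "_", a)
  to_rc <- function(v) c(((idx[v] - 1L) %% nr) + 1L, ((idx[v] - 1L) %/% nr) + 1L)
  walk <- function(v0, v1) {
    path <- c(v0, v1)
    assign(ekey(v0, v1), TRUE, envir = used)
    prev <- v0; cur <- v1
    while (dg[cur] == 2L) {
      nxt <- adj[[cur]][adj[[cur]] != prev]
      if (length(nxt) != 1L) break
      if (exists(ekey(cur, nxt), envir = used)) break  # closed back on itself
      assign(ekey(cur, nxt), TRUE, envir = used)
      path <- c(path, nxt)
      prev <- cur; cur <- nxt
    }
    path
  }
  nodes <- which(dg != 2L)
  for (v in nodes) {
    for (w in adj[[v]]) {
      if (exists(ekey(v, w), envir = used)) next
      path <- walk(v, w)
      segments[[length(segments) + 1L]] <-
        t(vapply(path, to_rc, integer(2L)))
    }
  }
  # pure cycles: all remaining vertices have degree 2 and untraversed edges
  for (v in seq_along(idx)) {
    if (dg[v] != 2L) next
    for (w in adj[[v]]) {
      if (exists(ekey(v, w), envir = used)) next
      path <- walk(v, w)
      # close the ring explicitly by returning to the anchor
      if (path[length(path)] != v) path <- c(path, v)
      segments[[length(segments) + 1L]] <-
        t(vapply(path, to_rc, integer(2L)))
    }
  }
  lapply(segments, function(m) { colnames(m) <- c("row", "col"); m })
}

#' @export
print.crown_topology <- function(x, ...) {
  cat("Skeleton topology: ", nrow(x$branch_points), " branch points, ",
      nrow(x$end_points), " end points, ", length(x$segments),
      " root segments\n", sep = "")
  invisible(x)
}

#' Validate segment reconstruction
#'
#' Checks that the union of all root-segment pixels, plus isolated pixels,
#' reproduces the skeleton pixel set exactly.
#'
#' @param g A \code{crown_topology}.
#' @param skel The skeleton it was built from.
#' @return \code{TRUE} when the reconstruction replicates the skeleton.
#' @export
validate_reconstruction <- function(g, skel) {
  S <- if (inherits(skel, "crown_skeleton")) skel$mask else skel
  rec <- matrix(FALSE, nrow(S), ncol(S))
  for (seg in g$segments) rec[seg] <- TRUE
  if (nrow(g$isolated)) rec[g$isolated] <- TRUE
  !any(rec & !S) && !any(S & !rec)
}

#' Number of root tips
#'
#' The count of skeleton end points (degree-1 pixels). For a clamped crown
#' the top attachment point contributes one tip.
#'
#' @param g A \code{crown_topology}.
#' @return Non-negative integer.
#' @export
count_tips <- function(g) nrow(g$end_points)
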
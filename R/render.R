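# Rendering of segmented and feature-overlay images.

#' Render the segmented (binary) image
#'
#' @param mask Logical foreground mask.
#' @return Numeric matrix in [0, 1]: root pixels black, background white.
#' @export
render_segmented <- function(mask) {
  1 - mask * 1
}

#' Render the feature-overlay image
#'
#' Draws the extracted features on the segmented image: the convex hull as a
#' blue polygon, boundary and skeleton pixels in red, the distance-transform
#' magnitude in the green channel, and every hole filled with a
#' pseudo-random color determined by (seed, hole index), so renders are
#' byte-reproducible.
#'
#' @param mask Logical foreground mask.
#' @param dmap Distance map.
#' @param skel A \code{crown_skeleton}.
#' @param g A \code{crown_topology} (currently only carried for interface
#'   symmetry with the analysis stages).
#' @param hull Convex hull vertices ((row, col) matrix).
#' @param contours Optional precomputed contours.
#' @param seed Integer key for the hole colors.
#' @return h x w x 3 array in [0, 1].
#' @export
render_feature_image <- function(mask, dmap, skel, g, hull,
                                 contours = NULL, seed = 1L) {
  nr <- nrow(mask); nc <- ncol(mask)
  R <- matrix(1, nr, nc); G <- matrix(1, nr, nc); B <- matrix(1, nr, nc)
  # segmented base: root pixels black
  R[mask] <- 0; G[mask] <- 0; B[mask] <- 0
  # distance transform in the green channel
  dmx <- max(dmap)
  if (dmx > 0) G[mask] <- (dmap[mask] / dmx)
  # holes in deterministic pseudo-random colors
  lab <- label_components(!mask, 4L)
  if (max(lab) > 0L) {
    border <- unique(c(lab[1L, ], lab[nr, ], lab[, 1L], lab[, nc]))
    holes <- setdiff(sort(unique(lab[lab > 0L])), border)
    for (i in seq_along(holes)) {
      col3 <- hole_color(seed, i)
      sel <- lab == holes[i]
      R[sel] <- col3[1L]; G[sel] <- col3[2L]; B[sel] <- col3[3L]
    }
  }
  # boundary and skeleton pixels in red
  if (is.null(contours)) contours <- extract_contours(mask)
  for (cn in contours) {
    R[cn$points] <- 1; G[cn$points] <- 0; B[cn$points] <- 0
  }
  S <- skel$mask
  R[S] <- 1; G[S] <- 0; B[S] <- 0
  # convex hull polygon in blue
  if (!is.null(hull) && nrow(hull) >= 2L) {
    k <- nrow(hull)
    for (i in seq_len(k)) {
      j <- if (i == k) 1L else i + 1L
      px <- bresenham(hull[i, ], hull[j, ])
      R[px] <- 0; G[px] <- 0; B[px] <- 1
    }
  }
  arr <- array(0, c(nr, nc, 3L))
  arr[, , 1L] <- R; arr[, , 2L] <- G; arr[, , 3L] <- B
  arr
}

# deterministic color from a small hash of (seed, index); avoids touching
# the global RNG stream
hole_color <- function(seed, index) {
  h <- (as.numeric(seed) * 2654435761 + index * 40503) %% 2^31
  r <- (h %% 200) / 255 + 0.1
  g <- ((h %/% 200) %% 200) / 255 + 0.1
  b <- ((h %/% 40000) %% 200) / 255 + 0.1
  pmin(c(r, g, b), 1)
}
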
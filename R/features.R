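# Feature extraction: the 27 per-image phenes.

#' Root count profile from horizontal line scans
#'
#' Scans each image row left to right and counts background-to-foreground
#' transitions (a foreground pixel in the first column counts as one). The
#' profile spans only the rows of the foreground's vertical extent, so frame
#' rows above and below the crown do not dilute the summary statistics.
#'
#' @param mask Logical foreground mask.
#' @return Integer vector of per-row root counts (length = vertical extent;
#'   empty for an empty mask).
#' @export
root_count_profile <- function(mask) {
  if (!any(mask)) return(integer(0))
  nc <- ncol(mask)
  left <- cbind(FALSE, mask[, -nc, drop = FALSE])
  counts <- rowSums(mask & !left)
  rows <- range(which(rowSums(mask) > 0))
  as.integer(counts[rows[1L]:rows[2L]])
}

#' Median and maximum root number
#'
#' @param profile Integer vector from \code{\link{root_count_profile}}.
#' @return List with \code{median} (even-length profiles: mean of the
#'   central pair) and \code{maximum}; both 0 for an empty profile.
#' @export
median_max_roots <- function(profile) {
  if (!length(profile)) return(list(median = 0, maximum = 0L))
  list(median = stats::median(profile), maximum = max(profile))
}

#' Spatial extent of the crown
#'
#' @param mask Logical foreground mask.
#' @return List with \code{maximum_width} (columns spanned), \code{depth}
#'   (rows spanned) and \code{width_to_depth_ratio}; all 0 when empty.
#' @export
extent_metrics <- function(mask) {
  if (!any(mask))
    return(list(maximum_width = 0L, depth = 0L, width_to_depth_ratio = 0))
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  w <- cc[2L] - cc[1L] + 1L
  d <- rr[2L] - rr[1L] + 1L
  list(maximum_width = w, depth = d, width_to_depth_ratio = w / d)
}

#' Area, convexity and perimeter measures
#'
#' Network area is the foreground pixel count. The convex area is the
#' shoelace area of the convex hull of foreground pixel centers (degenerate
#' hulls have area 0 and solidity 0). The perimeter sums chain step lengths
#' along all boundary contours: 1 per orthogonal step, sqrt(2) per diagonal
#' step.
#'
#' @param mask Logical foreground mask.
#' @param contours Optional precomputed result of
#'   \code{\link{extract_contours}}.
#' @return List with \code{network_area}, \code{convex_area},
#'   \code{solidity}, \code{perimeter} and \code{hull} (hull vertices,
#'   (row, col)).
#' @export
area_metrics <- function(mask, contours = NULL) {
  net <- sum(mask)
  if (net == 0L)
    return(list(network_area = 0L, convex_area = 0, solidity = 0,
                perimeter = 0, hull = matrix(0L, 0L, 2L)))
  pts <- which(mask, arr.ind = TRUE)
  hull_idx <- grDevices::chull(pts[, 2L], pts[, 1L])
  hull <- pts[hull_idx, , drop = FALSE]
  ca <- shoelace_area(hull)
  if (is.null(contours)) contours <- extract_contours(mask)
  per <- sum(vapply(contours,
                    function(cn) chain_length(cn$points, closed = TRUE), 0))
  list(network_area = net, convex_area = ca,
       solidity = if (ca > 0) net / ca else 0,
       perimeter = per, hull = hull)
}

shoelace_area <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) return(0)
  x <- pts[, 2L]; y <- pts[, 1L]
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Diameter statistics from skeleton radii
#'
#' Every skeleton pixel carries radius = its distance-map value; its root
#' diameter is twice that. Volume sums the per-pixel cross-section areas
#' (pi r^2 per unit skeleton step) and surface area the per-pixel
#' circumferences (2 pi r).
#'
#' @param skel A \code{crown_skeleton}.
#' @param bin_edges Two ascending diameter edges (same units as the radii,
#'   i.e. pixels) defining the fine/medium/coarse histogram bins
#'   [0, e1), [e1, e2), [e2, Inf).
#' @return List with \code{average_diameter}, \code{median_diameter},
#'   \code{maximum_diameter}, \code{volume}, \code{surface_area} and
#'   \code{frequencies} (length-3, summing to 1 for a non-empty skeleton).
#' @export
diameter_metrics <- function(skel, bin_edges) {
  r <- skel$radius[skel$mask]
  if (!length(r))
    return(list(average_diameter = 0, median_diameter = 0,
                maximum_diameter = 0, volume = 0, surface_area = 0,
                frequencies = c(fine = 0, medium = 0, coarse = 0)))
  d <- 2 * r
  f <- c(sum(d < bin_edges[1L]),
         sum(d >= bin_edges[1L] & d < bin_edges[2L]),
         sum(d >= bin_edges[2L])) / length(d)
  names(f) <- c("fine", "medium", "coarse")
  list(average_diameter = mean(d), median_diameter = stats::median(d),
       maximum_diameter = max(d),
       volume = sum(pi * r^2), surface_area = sum(2 * pi * r),
       frequencies = f)
}

#' Total root length
#'
#' Sum of Euclidean step lengths over all root segments (1 per orthogonal
#' step, sqrt(2) per diagonal step); every skeleton edge is counted exactly
#' once.
#'
#' @param g A \code{crown_topology}.
#' @return Length in pixels.
#' @export
total_root_length <- function(g) {
  sum(vapply(g$segments, function(seg) chain_length(seg, closed = FALSE), 0))
}

#' Root area below the widest point
#'
#' Counts foreground pixels strictly below (larger row than) the skeleton
#' pixel of maximum radius. Radius ties are broken toward the smallest row,
#' then smallest column.
#'
#' @param mask Logical foreground mask.
#' @param skel A \code{crown_skeleton}.
#' @return Pixel count (0 for an empty skeleton).
#' @export
lower_root_area <- function(mask, skel) {
  px <- skeleton_pixels(skel)
  if (!nrow(px)) return(0L)
  px <- px[order(-px$radius, px$row, px$col), ]
  r0 <- px$row[1L]
  if (r0 >= nrow(mask)) return(0L)
  sum(mask[(r0 + 1L):nrow(mask), , drop = FALSE])
}

#' Hole count and average hole size
#'
#' Holes are 4-connected background components fully enclosed by foreground
#' (components touching the image border are open background, not holes).
#'
#' @param mask Logical foreground mask.
#' @return List with \code{holes} and \code{average_hole_size} (mean pixel
#'   count, 0 when there are no holes).
#' @export
hole_metrics <- function(mask) {
  lab <- label_components(!mask, 4L)
  if (max(lab) == 0L) return(list(holes = 0L, average_hole_size = 0))
  border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
  sizes <- tabulate(lab[lab > 0L])
  keep <- setdiff(seq_along(sizes), border)
  if (!length(keep)) return(list(holes = 0L, average_hole_size = 0))
  list(holes = length(keep), average_hole_size = mean(sizes[keep]))
}

#' Per-pixel root orientation and angle frequencies
#'
#' For every skeleton pixel, all skeleton pixels inside a centered square
#' window are collected and the orientation of their leading principal
#' component is computed from the 2x2 coordinate covariance; the angle is
#' folded to [0, 90] degrees from the horizontal. The average over all
#' skeleton pixels is the average root orientation, and the angles are
#' binned into shallow [0, 30), medium [30, 60) and steep [60, 90]
#' frequencies. A window holding fewer than two pixels falls back to the
#' chord angle of the containing segment (0 for an isolated pixel).
#'
#' @param skel A \code{crown_skeleton}.
#' @param g A \code{crown_topology} for the chord fallback.
#' @param window_px Window side in pixels (>= 3); the box spans
#'   \code{floor(window_px / 2)} pixels above/left and the remainder
#'   below/right.
#' @return List with \code{average_root_orientation} (degrees) and
#'   \code{frequencies} (length-3, summing to 1 for a non-empty skeleton).
#' @export
orientation_metrics <- function(skel, g, window_px = 40L) {
  if (window_px < 3L) stop("`window_px` must be >= 3", call. = FALSE)
  S <- skel$mask
  ij <- which(S, arr.ind = TRUE)
  n <- nrow(ij)
  if (n == 0L)
    return(list(average_root_orientation = 0,
                frequencies = c(shallow = 0, medium = 0, steep = 0)))
  if (n == 1L)
    return(list(average_root_orientation = 0,
                frequencies = c(shallow = 1, medium = 0, steep = 0)))
  nr <- nrow(S); nc <- ncol(S)
  rmat <- matrix(seq_len(nr), nr, nc)
  cmat <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  Si <- S * 1
  I0 <- integral_image(Si)
  Ir <- integral_image(Si * rmat);  Ic <- integral_image(Si * cmat)
  Irr <- integral_image(Si * rmat^2); Icc <- integral_image(Si * cmat^2)
  Irc <- integral_image(Si * rmat * cmat)
  h_lo <- window_px %/% 2L
  h_hi <- window_px - h_lo - 1L
  rlo <- pmax(1L, ij[, 1L] - h_lo); rhi <- pmin(nr, ij[, 1L] + h_hi)
  clo <- pmax(1L, ij[, 2L] - h_lo); chi <- pmin(nc, ij[, 2L] + h_hi)
  m  <- window_sum(I0, rlo, rhi, clo, chi)
  sr <- window_sum(Ir, rlo, rhi, clo, chi)
  sc <- window_sum(Ic, rlo, rhi, clo, chi)
  srr <- window_sum(Irr, rlo, rhi, clo, chi)
  scc <- window_sum(Icc, rlo, rhi, clo, chi)
  src <- window_sum(Irc, rlo, rhi, clo, chi)
  cov_rr <- srr / m - (sr / m)^2
  cov_cc <- scc / m - (sc / m)^2
  cov_rc <- src / m - (sr / m) * (sc / m)
  theta <- 0.5 * atan2(2 * cov_rc, cov_cc - cov_rr)
  ang <- abs(theta) * 180 / pi
  ang[ang > 90] <- 180 - ang[ang > 90]
  lone <- m < 2
  if (any(lone)) ang[lone] <- segment_chord_angle(g, ij[lone, , drop = FALSE])
  f <- c(shallow = sum(ang < 30), medium = sum(ang >= 30 & ang < 60),
         steep = sum(ang >= 60)) / n
  list(average_root_orientation = mean(ang), frequencies = f)
}

# chord angle (degrees from horizontal, folded to [0, 90]) of the segment
# containing each query pixel; 0 when the pixel is isolated
segment_chord_angle <- function(g, pix) {
  out <- numeric(nrow(pix))
  for (i in seq_len(nrow(pix))) {
    a <- 0
    for (seg in g$segments) {
      hit <- seg[, 1L] == pix[i, 1L] & seg[, 2L] == pix[i, 2L]
      if (any(hit)) {
        dr <- seg[nrow(seg), 1L] - seg[1L, 1L]
        dc <- seg[nrow(seg), 2L] - seg[1L, 2L]
        if (dr != 0 || dc != 0) {
          a <- abs(atan2(dr, dc)) * 180 / pi
          if (a > 90) a <- 180 - a
        }
        break
      }
    }
    out[i] <- a
  }
  out
}

#' Assemble the 27-phene feature set
#'
#' Populates the full feature row from the per-stage metric lists. Called by
#' \code{\link{analyze_image}}; exported for building feature rows from
#' custom pipelines.
#'
#' @param file_name Image identifier.
#' @param profile_stats,extent,areas,diam,orient Stage outputs (see the
#'   corresponding metric functions).
#' @param n_tips Tip count from \code{\link{count_tips}}.
#' @param length_px Total root length from \code{\link{total_root_length}}.
#' @param lower_area Result of \code{\link{lower_root_area}}.
#' @param holes Result of \code{\link{hole_metrics}}.
#' @param elapsed_seconds Wall-clock analysis time for this image.
#' @return A \code{crown_features} row in pixel units.
#' @export
assemble_features <- function(file_name, profile_stats, extent, areas, diam,
                              orient, n_tips, length_px, lower_area, holes,
                              elapsed_seconds = 0) {
  vals <- c(
    median_number_of_roots = profile_stats$median,
    maximum_number_of_roots = profile_stats$maximum,
    number_of_root_tips = n_tips,
    total_root_length = length_px,
    depth = extent$depth,
    maximum_width = extent$maximum_width,
    width_to_depth_ratio = extent$width_to_depth_ratio,
    network_area = areas$network_area,
    convex_area = areas$convex_area,
    solidity = areas$solidity,
    perimeter = areas$perimeter,
    average_diameter = diam$average_diameter,
    median_diameter = diam$median_diameter,
    maximum_diameter = diam$maximum_diameter,
    volume = diam$volume,
    surface_area = diam$surface_area,
    lower_root_area = lower_area,
    holes = holes$holes,
    average_hole_size = holes$average_hole_size,
    average_root_orientation = orient$average_root_orientation,
    fine_diameter_frequency = unname(diam$frequencies[1L]),
    medium_diameter_frequency = unname(diam$frequencies[2L]),
    coarse_diameter_frequency = unname(diam$frequencies[3L]),
    shallow_angle_frequency = unname(orient$frequencies[1L]),
    medium_angle_frequency = unname(orient$frequencies[2L]),
    steep_angle_frequency = unname(orient$frequencies[3L]),
    computational_time = elapsed_seconds
  )
  new_feature_set(vals, file_name = file_name, units = "px")
}
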
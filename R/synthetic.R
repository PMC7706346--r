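# Synthetic silhouette generator with exact ground truth.
#
# Emulates the backlit imaging hardware: near-white background (245),
# near-black roots (15), mildly jagged edges from supersampled anti-aliased
# rasterization. Used for wire-style physical calibration re-enactments and
# for crown-shaped validation images with known length, tips, widths and
# angles.

.bg_intensity <- 245
.fg_intensity <- 15

# Rasterize stroked segments (round caps) at `supersample` resolution and
# downsample by block averaging. `segments` is a data frame with columns
# r0, c0, r1, c1 (continuous (row, col) coordinates; pixel (i, j) center is
# (i, j)) and width (stroke width in px).
render_strokes <- function(segments, nr, nc, supersample = 4L,
                           bg = .bg_intensity, fg = .fg_intensity) {
  s <- as.integer(supersample)
  fine <- matrix(FALSE, nr * s, nc * s)
  for (i in seq_len(nrow(segments))) {
    a <- c(segments$r0[i], segments$c0[i])
    b <- c(segments$r1[i], segments$c1[i])
    hw <- segments$width[i] / 2
    rlo <- max(1L, floor((min(a[1L], b[1L]) - hw - 1) * s))
    rhi <- min(nr * s, ceiling((max(a[1L], b[1L]) + hw + 1) * s))
    clo <- max(1L, floor((min(a[2L], b[2L]) - hw - 1) * s))
    chi <- min(nc * s, ceiling((max(a[2L], b[2L]) + hw + 1) * s))
    if (rlo > rhi || clo > chi) next
    rr <- rlo:rhi; cc <- clo:chi
    # fine-cell centers in coarse pixel coordinates
    rcent <- (rr - 0.5) / s + 0.5
    ccent <- (cc - 0.5) / s + 0.5
    pts <- cbind(rep(rcent, times = length(cc)),
                 rep(ccent, each = length(rr)))
    d <- point_segment_dist(pts, a, b)
    hit <- matrix(d <= hw, length(rr), length(cc))
    fine[rr, cc] <- fine[rr, cc] | hit
  }
  # block-average the s x s fine cells of each coarse pixel
  g1 <- rowsum(fine * 1, rep(seq_len(nr), each = s))
  cover <- t(rowsum(t(g1), rep(seq_len(nc), each = s))) / (s * s)
  out <- round(bg - (bg - fg) * cover)
  dimnames(out) <- NULL
  out
}

#' Synthetic straight wire silhouette
#'
#' Renders one dark anti-aliased bar of known physical diameter and length
#' at a given image scale and angle, the synthetic stand-in for imaging a
#' copper wire of micrometer-measured diameter on the backlight.
#'
#' @param diameter_mm Wire diameter in mm (must map to >= 1 px).
#' @param length_mm Wire length in mm.
#' @param px_per_mm Image scale in pixels per mm.
#' @param angle_deg Wire angle in degrees from the horizontal.
#' @return List with \code{image} (grayscale matrix) and \code{truth}
#'   (diameter/length in px and mm, angle, tip count).
#' @examples
#' w <- make_wire_image(2.57, length_mm = 30, px_per_mm = 13.63866)
#' w$truth$diameter_px
#' @export
make_wire_image <- function(diameter_mm, length_mm = 40,
                            px_per_mm = 13.63866, angle_deg = 90) {
  d_px <- diameter_mm * px_per_mm
  if (d_px < 1)
    stop("sub-pixel wire: diameter maps to ", round(d_px, 2),
         " px (< 1 px floor)", call. = FALSE)
  l_px <- length_mm * px_per_mm
  th <- angle_deg * pi / 180
  dr <- abs(l_px * sin(th)); dc <- abs(l_px * cos(th))
  margin <- d_px / 2 + 6
  nr <- ceiling(dr + 2 * margin); nc <- ceiling(dc + 2 * margin)
  r0 <- margin + if (sin(th) >= 0) 0 else dr
  c0 <- margin + if (cos(th) >= 0) 0 else dc
  seg <- data.frame(r0 = r0, c0 = c0,
                    r1 = r0 + l_px * sin(th), c1 = c0 + l_px * cos(th),
                    width = d_px)
  img <- render_strokes(seg, nr, nc)
  truth <- list(diameter_mm = diameter_mm, diameter_px = d_px,
                length_mm = length_mm, length_px = l_px,
                angle_deg = angle_deg, tip_count = 2L)
  list(image = img, truth = truth)
}

#' Synthetic root crown silhouette with ground truth
#'
#' Draws a vertical main axis clamped at the top image border with
#' \code{n_laterals} straight lateral roots leaving it at angles drawn from
#' the requested regime (shallow: 5-25, mixed: 10-80, steep: 65-85 degrees
#' from the horizontal), alternating sides, with per-stroke widths drawn
#' from \code{width_range_px}. Tips stay inside the frame and are mutually
#' separated. The returned truth records the exact centerline lengths, the
#' tip count (one per lateral, plus the axis bottom tip and the top
#' attachment point), per-segment angles and widths, and the exact stroke
#' extents. Deterministic for a given seed.
#'
#' @param n_laterals Number of lateral roots (>= 0).
#' @param angle_regime One of "shallow", "mixed", "steep".
#' @param width_range_px Range the stroke widths are drawn from.
#' @param seed Integer RNG seed.
#' @param height,width Image size in pixels.
#' @return List with \code{image} and \code{truth} (fields
#'   \code{total_length_px}, \code{tip_count}, \code{max_width_px},
#'   \code{depth_px}, \code{angles_deg}, \code{widths_px}, \code{seed}).
#' @export
make_synthetic_crown <- function(n_laterals = 25L,
                                 angle_regime = c("mixed", "shallow", "steep"),
                                 width_range_px = c(3, 7),
                                 seed = 1L,
                                 height = 480L, width = 360L) {
  angle_regime <- match.arg(angle_regime)
  if (n_laterals < 0L) stop("`n_laterals` must be >= 0", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  c0 <- width / 2
  axis_w <- max(width_range_px)
  depth0 <- round(0.85 * height)
  segs <- data.frame(r0 = -axis_w, c0 = c0, r1 = depth0, c1 = c0,
                     width = axis_w)
  angles <- 90; widths <- axis_w
  lat_len <- numeric(0)
  if (n_laterals > 0L) {
    arange <- switch(angle_regime, shallow = c(5, 25), mixed = c(10, 80),
                     steep = c(65, 85))
    attach_r <- seq(40, depth0 - 30, length.out = n_laterals) +
      stats::runif(n_laterals, -4, 4)
    side <- rep(c(1, -1), length.out = n_laterals)
    # clearance between stroke centerlines so laterals never fuse outside
    # their junction with the axis: half-widths plus the edge-smoothing
    # tolerance (2 px) plus the anti-aliasing blur
    clear <- axis_w / 2 + max(width_range_px) / 2 + 4
    th <- stats::runif(n_laterals, arange[1L], arange[2L])
    for (sd in c(1, -1)) {
      k <- which(side == sd)
      if (length(k) < 1L) next
      # per side: angles ascend with depth, so the rays fan out without
      # crossing; cap each angle so (a) the next same-side attachment sits
      # at least `clear` off this ray and (b) the ray clears the axis tip
      th[k] <- sort(th[k])
      for (j in seq_along(k)) {
        i <- k[j]
        cap <- atan((depth0 - attach_r[i]) / clear) * 180 / pi
        if (j < length(k)) {
          dr_next <- attach_r[k[j + 1L]] - attach_r[i]
          cap <- min(cap, acos(min(1, clear / dr_next)) * 180 / pi)
        }
        th[i] <- min(th[i], cap)
      }
      # re-impose the ascending fan after capping (a capped deep lateral
      # must also cap everything above it, or rays would cross)
      if (length(k) > 1L) {
        for (j in (length(k) - 1L):1L) {
          th[k[j]] <- min(th[k[j]], th[k[j + 1L]])
        }
      }
    }
    for (i in seq_len(n_laterals)) {
      thr <- th[i] * pi / 180
      w <- stats::runif(1, width_range_px[1L], width_range_px[2L])
      dirv <- c(sin(thr), side[i] * cos(thr))   # downward, outward
      margin <- w / 2 + 6
      # longest length keeping the tip inside the frame
      lmax_r <- (height - margin - attach_r[i]) / dirv[1L]
      lmax_c <- if (side[i] > 0) (width - margin - c0) / dirv[2L] else
        (margin - c0) / dirv[2L]
      lmax <- max(10, min(lmax_r, lmax_c))
      len <- stats::runif(1, 0.55, 0.95) * lmax
      segs <- rbind(segs, data.frame(
        r0 = attach_r[i], c0 = c0,
        r1 = attach_r[i] + len * dirv[1L], c1 = c0 + len * dirv[2L],
        width = w))
      angles <- c(angles, th[i])
      widths <- c(widths, w)
      lat_len <- c(lat_len, len)
    }
  }
  img <- render_strokes(segs, height, width)
  # exact stroke extents (round caps; the axis cap above row 0 is clipped)
  r_ext <- pmin(height, segs$r1 + segs$width / 2)
  c_lo <- pmin(segs$c0, segs$c1) - segs$width / 2
  c_hi <- pmax(segs$c0, segs$c1) + segs$width / 2
  truth <- list(
    total_length_px = depth0 + sum(lat_len),
    tip_count = as.integer(n_laterals) + 2L,
    max_width_px = max(c_hi) - min(c_lo),
    depth_px = max(r_ext),
    angles_deg = angles, widths_px = widths,
    lateral_lengths_px = lat_len,
    seed = seed)
  list(image = img, truth = truth)
}

#' Degenerate-input test suite
#'
#' Small pathological silhouettes paired with notes on the expected
#' behavior: empty image, all-foreground image, single dark pixel, one-pixel
#' line, border-touching bar, and a ring enclosing a hole. All must produce
#' a valid 27-phene row without error.
#'
#' @param size Side of the square test images.
#' @return Named list; each element has \code{image} and \code{note}.
#' @export
make_degenerate_suite <- function(size = 32L) {
  bg <- .bg_intensity; fg <- .fg_intensity
  blank <- matrix(bg, size, size)
  all_fg <- matrix(fg, size, size)
  single <- blank; single[size %/% 2L, size %/% 2L] <- fg
  line <- blank; line[size %/% 2L, 5:(size - 5L)] <- fg
  border <- blank; border[1:(size - 8L), (size %/% 2L - 1L):(size %/% 2L + 1L)] <- fg
  ring <- blank
  ring[8:24, 8:24] <- fg; ring[12:20, 12:20] <- bg
  list(
    empty = list(image = blank, note = "all features zero"),
    all_foreground = list(image = all_fg, note = "no holes; solidity ~ 1"),
    single_pixel = list(image = single,
                        note = "area 1, degenerate hull, perimeter 0"),
    one_px_line = list(image = line, note = "two tips, depth 1"),
    border_touching = list(image = border,
                           note = "contour closed along the border"),
    ring = list(image = ring, note = "exactly one hole")
  )
}
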
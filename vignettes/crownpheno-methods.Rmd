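---
title: "Methods: from root crown silhouettes to 27 phenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from root crown silhouettes to 27 phenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`crownpheno` measures excavated root crowns from backlit silhouette
images. This vignette documents the model behind each stage, the tunable
parameters, the synthetic data used for validation, and the numerical
choices made where the design was genuinely open. Coordinates are 1-based
`(row, col)` with row 1 at the image top, so rows run along the depth axis
and columns along the width axis.

## Assumptions about the input

The imaging rig this pipeline is built for produces near-binary images:
the background is a bright, uniform backlight and the root crown is a dark
silhouette clamped at the top of the frame. Consequently:

* segmentation is a plain global threshold (`threshold_level`, default
  128, on the 0–255 intensity scale) — no adaptive thresholding, no color;
* a foreground region touching the image border is normal (the clamped
  stem enters from the top); contours are closed along the border and the
  frame beyond the image counts as background for the distance transform;
* grayscale or already-binary images from other sources are accepted, and
  `invert_foreground` flips the rule for bright-on-dark material.

## Edge smoothing

Thresholded silhouette edges carry jags of roughly one to two pixels.
Every such jag produces a short false lateral in any skeleton, so the mask
boundary is simplified before skeletonization. Each contour — one outer
ring per 8-connected component, one ring per enclosed hole, traced by
Moore neighbor tracing — is reduced with the Ramer–Douglas–Peucker (RDP)
algorithm: the chord between two anchor points replaces the contour run
when no intermediate point deviates from it by more than
`rdp_epsilon_px` (default 2 px, matching the jag amplitude; distances are
point-to-segment with endpoint clamping). Closed rings are split at the
point farthest from the ring start and each half simplified; because the
two split anchors are retained unconditionally by the recursion, a greedy
relaxation pass afterwards removes any ring vertex whose span is already
within tolerance of its neighbors' chord — without it, an anchor that
happens to sit on a bump would survive simplification. Simplified outer
polygons are re-rasterized as filled polygons (even–odd scanline fill over
pixel centers plus the Bresenham boundary); hole polygons are re-subtracted
(strict interior minus the boundary, which consists of root pixels).

Consequences worth knowing: pixels are both added and removed; component
count is preserved (every component keeps at least its rasterized
boundary), but a hole smaller than about `rdp_epsilon_px`² can close —
at the default tolerance a 2 × 2 px hole disappears while a 4 × 4 px hole
survives. On silhouettes with realistic root widths (16–26 px at a field
resolution of ~12.8 px/mm) the smoothed mask agrees with the raw one with
Jaccard ≥ 0.95.

## Distance transform and medial axis

The Euclidean distance transform is exact (computed via `EBImage::distmap`
on a background-padded copy, verified against brute force in the tests),
not a chamfer approximation, because every skeleton radius — and therefore
every diameter, the volume and the surface area — is read directly off it.

The medial axis is extracted as the *ridge* of the distance map. The
pixel test had to be designed here, and three candidates were evaluated:

* a symmetric local-maximum test over the four principal directions
  (keep when the value is ≥ both neighbors and > one of them along any
  axis) admits every convex corner of the digitized boundary — each
  staircase step of an oblique edge — and floods the result with spurs;
* the maximal-inscribed-disk criterion (drop a pixel when a neighbor's
  disk contains its own) only fires when the nearest-background direction
  passes exactly through a neighbor, i.e. at multiples of 45°, and keeps
  most of the stroke interior at other angles.

The implemented rule is non-maximum selection transverse to the distance
gradient: at each foreground pixel the central-difference gradient of the
distance map is quantized to the nearest of the four principal axes, and
the pixel is kept when its value is not smaller than both neighbors along
that axis and strictly larger than the neighbor in the positive axis
direction. The asymmetric strictness breaks plateau ties so that
even-width roots yield a one-pixel crest instead of a two-pixel band
(bands whose sides join at both ends survive thinning as loops). Where
the gradient vanishes (junction centers, disk centers) all four axes are
tried with the symmetric rule, and 8-neighborhood summits — e.g. the
single widest point of the crown — are always kept, since a nearby larger
summit can skew the local gradient enough to shadow them.

Boundary pixels fail this test along their own gradient, so the ridge is
spur-free, but it is fragmented: where the crest runs between pixel rows
only the nearer row qualifies. Reconnection follows in three deterministic
passes:

1. **steepest ascent** — from every ridge end point, walk to the
   8-neighbor with the largest distance value (ties broken in N, NE, E,
   SE, S, SW, W, NW order), until a ridge pixel of another fragment is
   met; the walk is capped at four times the local radius and discarded
   if it terminates without connecting;
2. **geodesic fallback** — fragments still separated inside one mask
   component are joined by a minimum-cost spanning forest over shortest
   foreground paths (one multi-source breadth-first search, meetings
   scored by combined distance), so every mask component of at least four
   pixels carries exactly one skeleton component;
3. **Guo–Hall thinning** — the parallel two-subiteration thinning reduces
   the connected set to single-pixel width while preserving connectivity
   and end points; residual 2 × 2 blocks are resolved by deleting a simple
   pixel, and single-pixel dangles left where a two-wide crest met a
   through-path (an end point whose sole neighbor has reduced degree ≥ 3)
   are removed in two passes.

The speck and dangle hygiene in passes 1 and 3 removes one-to-two-pixel
artifacts of this particular crest detector and thinning order. It is not
a pruning of short root segments: segments of the final topology, however
short, are never filtered (true spur pruning is deliberately out of scope).

Two skeleton caveats are inherent to medial axes and shared with any
distance-ridge method: the skeleton ends about one radius short of each
root tip, and the per-pixel diameter 2·*r* overestimates odd pixel widths
by about one pixel (the ridge sits on a pixel center, not between two).
No bias correction is applied; the wire-calibration check absorbs this as
a regression intercept near −0.1 mm with slope ≈ 1.

## Topology

Skeletal degree is computed on the 8-neighborhood with redundancy
reduction: a diagonal neighbor is not counted when an orthogonal neighbor
adjacent to both pixels exists, so a staircase counts as one path, not
two. Branch points have degree ≥ 3 (degree-4 crossings are handled by the
same rule — a degree-*d* node terminates *d* segments), end points have
degree 1, and segments are maximal paths between such nodes with all
interior pixels of degree 2. Cycles without any branch point become one
closed segment anchored at their first pixel in scan order. Traversal
order is fixed (scan-order starting pixels, N→NW neighbor order), so
outputs are byte-reproducible. Every analysis validates that the union of
segment pixels (plus isolated pixels) reproduces the skeleton exactly.

The tip count is the number of end points. For a clamped crown the top
attachment contributes end points as well — usually two, because the
medial axis of a stroke cut by the frame border genuinely branches toward
the two cut corners. The synthetic truth books the attachment as one tip;
the residual +1 is well inside the ±10% recovery tolerance.

## Phenes

* **Root count profile**: per-row background→foreground transitions, rows
  restricted to the foreground's vertical extent (frame rows above and
  below the crown would otherwise drag the median toward zero). A root in
  column 1 counts as a transition. Median (mean of the central pair for
  even lengths) and maximum summarize the profile.
* **Extent**: depth and maximum width are bounding-box spans in rows and
  columns; their ratio is 0 when the mask is empty.
* **Areas**: network area is the foreground pixel count; convex area is
  the shoelace area of `grDevices::chull` on pixel centers (degenerate
  hulls give area 0 and solidity 0); perimeter sums chain steps (1
  orthogonal, √2 diagonal) over all contours, outer and holes alike.
* **Diameters**: 2·*r* per skeleton pixel; average, median, maximum;
  volume Σ π*r*² and surface area Σ 2π*r* (one pixel of skeleton length
  per term). Frequencies use half-open bins [0, e₁), [e₁, e₂), [e₂, ∞)
  with `diameter_bin_edges` in mm when a scale is supplied (default 2 and
  5 mm — fine, medium, coarse root classes), else in pixels.
* **Orientation**: for every skeleton pixel, all skeleton pixels in a
  centered `angle_window_px` square (default 40 px; the box spans
  ⌊w/2⌋ before and the remainder after the pixel) enter a 2 × 2
  coordinate covariance; the leading eigenvector angle, folded to
  [0°, 90°] from the horizontal, is the pixel's orientation. The window
  deliberately ignores segment membership: it is large enough to smooth
  small direction changes, and restricting it to the pixel's own segment
  would only matter within a window of a junction. Windows with fewer
  than two pixels fall back to the chord angle of the containing segment.
  Bins are [0°, 30°), [30°, 60°), [60°, 90°] — boundary angles land in
  the upper bin, 90° inclusively in the steep bin.
* **Holes**: 4-connected background components not touching the border
  (foreground is 8-connected, background 4-connected — the standard
  duality); count and mean pixel area.
* **Lower root area**: foreground pixels strictly below the
  maximum-radius skeleton pixel; radius ties break toward the smallest
  row, then column.
* **Computational time**: wall-clock seconds per image; excluded from
  unit conversion and from all correctness tests (hardware-dependent).

Unit conversion divides lengths by the scale *s* (px/mm), areas by *s*²,
volume by *s*³. Surface area is treated as area-like and volume as
volume-like because each sums a per-pixel quantity (circumference px,
disk area px²) over unit-length (1 px) skeleton steps — this keeps all
quantities dimensionally consistent. Counts, ratios, frequencies and
angles are unchanged.

## Synthetic data: what it emulates and what it does not

The generator renders strokes at 4× supersampling with round caps and
block-averages down, so silhouette edges carry the mild jaggedness of a
real camera after thresholding — this exercises the RDP smoothing stage
realistically. Background intensity is 245 and foreground 15, mimicking
the near-binary backlight images, so the default threshold 128 is
unambiguous.

`make_synthetic_crown()` draws a vertical axis clamped at the top border
and `n_laterals` straight laterals (default 25 on a 480 × 360 px canvas,
stroke widths drawn from 3–7 px), attached at evenly spaced, jittered
depths, alternating sides. Angles come from the requested regime —
shallow 5–25°, mixed 10–80°, steep 65–85° from the horizontal — and are
then constrained so the truth stays recoverable: per side, angles ascend
with attachment depth (rays fan out without crossing), each angle is
capped so the next same-side attachment and the axis bottom tip keep a
clearance of half the two stroke widths plus the 2 px smoothing tolerance
plus anti-aliasing blur, and caps propagate upward to preserve the
ascending fan. Within these constraints lengths are drawn to keep every
tip inside the frame. The truth records exact centerline lengths, tip
count (laterals + bottom tip + top attachment), per-segment angles and
widths, and analytic stroke extents.

What the generator does **not** emulate: crossing or overlapping roots
(real crowns produce hundreds of holes from overlaps; here holes are rare
sliver artifacts of junction wedges), curved roots, 3-D occlusion and
projection loss, soil debris, uneven illumination, and gray-level
gradients beyond the anti-aliased edge. Passing the recovery tests
therefore demonstrates that the *measurement chain* is correct on clean
geometry with known truth — not that field images are free of the
confounds the imaging hardware is designed to minimize.

Validation problem sizes, chosen to probe each property where it is
informative while keeping the full suite in the minutes range: 50 seeded
crowns at 480 × 360 px for truth recovery (tips ±10%, depth and width
±2 px, length ±5%, median diameter ±1.5 px against the length-weighted
median stroke width); wires of 0.20–2.57 mm at 13.63866 px/mm for the
physical calibration regression; single-angle wires at 15°, 45°, 75° for
angle-bin recovery (≥ 90% of pixels in the correct bin); masks up to
40 × 40 px for exhaustive oracle comparisons; and one 600 × 480 px crown
with 16–26 px strokes for the smoothing Jaccard bound.

## Numerical choices and degenerate inputs

Ties and tolerances: distance comparisons in the ridge test use an
absolute 1e-9 epsilon (exact Euclidean distances of equal configurations
compare equal); the gradient-plateau threshold is 0.1 px per px; scanline
fill includes pixel centers within 1e-9 of a polygon edge. All neighbor
scans use the fixed N, NE, E, SE, S, SW, W, NW order, component labels
follow scan order, and hole colors in renders hash (seed, hole index), so
every output — feature CSV and rendered images — is byte-reproducible
modulo the computational-time column.

Degenerate inputs produce valid rows, never errors: an empty mask yields
an all-zero feature row; an all-foreground image has solidity ≈ 1 and no
holes; a single pixel has network area 1, perimeter 0, degenerate hull,
orientation 0 with frequencies (1, 0, 0); a one-pixel line has two tips.
In batch mode a corrupt or unreadable file is logged, recorded as an
error-marker row, and the batch continues.

## Known limitations

* Chain-code length overestimates oblique strokes by up to ~8% (worst at
  22.5°); on mixed-angle crowns the net effect is within ±5% and partly
  cancels the ~one-radius shortening at each tip.
* Odd pixel widths carry a ≈ +1 px diameter bias (no pixel-center
  correction), visible as a small positive intercept in calibration.
* Holes at or below the smoothing tolerance squared close during edge
  smoothing.
* No pruning of short skeletal segments and no root-class labeling
  (axial vs lateral) — both deliberately out of scope.
* The root count profile counts collapsed or touching roots as one
  transition; it is a relative, not absolute, count under field
  conditions.
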
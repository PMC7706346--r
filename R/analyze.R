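# Per-image analysis pipeline.

#' Analyze one root crown silhouette
#'
#' Runs the full pipeline on a grayscale image or binary mask: thresholding,
#' contour-based edge smoothing, exact Euclidean distance transform, ridge
#' medial axis with connection and thinning, skeleton topology, and the 27
#' phenes. When the configuration carries \code{pixels_per_mm} the reported
#' features are in physical units (mm, mm^2, mm^3); the pixel-unit feature
#' row is always kept alongside.
#'
#' @param img Numeric matrix of grayscale intensities in [0, 255]
#'   (row 1 = top), or a logical mask (\code{TRUE} = root).
#' @param config A \code{\link{crown_config}}.
#' @param file_name Identifier recorded in the feature row.
#' @return A \code{crown_analysis} object: the smoothed mask, distance map,
#'   skeleton, topology, contours, convex hull, and \code{features}
#'   (a \code{crown_features} row; also \code{features_px} in pixel units).
#' @examples
#' syn <- make_synthetic_crown(n_laterals = 5, seed = 1,
#'                             height = 160, width = 120)
#' res <- analyze_image(syn$image, crown_config())
#' res$features$number_of_root_tips
#' @export
analyze_image <- function(img, config = crown_config(), file_name = "image") {
  t0 <- proc.time()[["elapsed"]]
  if (is.logical(img)) {
    raw <- img
  } else {
    raw <- threshold_image(img, config$threshold_level,
                           invert = config$invert_foreground)
  }
  mask <- smooth_mask(raw, config$rdp_epsilon_px)
  dmap <- distance_transform(mask)
  skel <- connect_skeleton(extract_medial_axis(dmap, mask), mask)
  g <- build_topology(skel)
  if (!validate_reconstruction(g, skel))
    warning("segment reconstruction does not replicate the skeleton for ",
            file_name, call. = FALSE)
  contours <- extract_contours(mask)
  profile <- root_count_profile(mask)
  pstats <- median_max_roots(profile)
  extent <- extent_metrics(mask)
  areas <- area_metrics(mask, contours)
  edges_px <- config$diameter_bin_edges
  if (!is.null(config$pixels_per_mm))
    edges_px <- edges_px * config$pixels_per_mm
  diam <- diameter_metrics(skel, edges_px)
  orient <- orientation_metrics(skel, g, config$angle_window_px)
  lower <- lower_root_area(mask, skel)
  holes <- hole_metrics(mask)
  elapsed <- proc.time()[["elapsed"]] - t0
  feats_px <- assemble_features(file_name, pstats, extent, areas, diam,
                                orient, count_tips(g), total_root_length(g),
                                lower, holes, elapsed_seconds = elapsed)
  feats <- if (is.null(config$pixels_per_mm)) feats_px else
    convert_units(feats_px, config$pixels_per_mm)
  structure(list(file_name = file_name, config = config,
                 mask_raw = raw, mask = mask, dmap = dmap, skeleton = skel,
                 topology = g, contours = contours, hull = areas$hull,
                 profile = profile, features_px = feats_px,
                 features = feats),
            class = "crown_analysis")
}

#' @export
print.crown_analysis <- function(x, ...) {
  cat("Root crown analysis of '", x$file_name, "'\n", sep = "")
  cat("  image: ", nrow(x$mask), " x ", ncol(x$mask), " px, ",
      sum(x$mask), " root pixels\n", sep = "")
  cat("  skeleton: ", sum(x$skeleton$mask), " pixels, ",
      nrow(x$topology$end_points), " tips, ",
      nrow(x$topology$branch_points), " branch points\n", sep = "")
  cat("  units: ", attr(x$features, "units"), "\n", sep = "")
  invisible(x)
}

#' @export
summary.crown_analysis <- function(object, ...) {
  print(object$features)
  invisible(object$features)
}

#' Display the feature-overlay rendering of an analysis
#'
#' @param x A \code{crown_analysis}.
#' @param seed Seed for the deterministic hole colors.
#' @param ... Passed to \code{\link[graphics]{plot.new}} machinery (unused).
#' @export
plot.crown_analysis <- function(x, seed = 1L, ...) {
  arr <- render_feature_image(x$mask, x$dmap, x$skeleton, x$topology,
                              x$hull, contours = x$contours, seed = seed)
  op <- graphics::par(mar = c(0, 0, 1, 0))
  on.exit(graphics::par(op))
  graphics::plot(c(0, ncol(x$mask)), c(0, nrow(x$mask)), type = "n",
                 asp = 1, axes = FALSE, xlab = "", ylab = "",
                 main = x$file_name)
  graphics::rasterImage(arr, 0, 0, ncol(x$mask), nrow(x$mask))
  invisible(x)
}
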
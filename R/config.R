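#' Analysis configuration
#'
#' Bundle of all tunable options of the root crown analysis pipeline.
#' Defaults reproduce the standard configuration for backlit silhouettes:
#' dark roots (intensity below \code{threshold_level}) on a bright
#' background, edge smoothing at a 2 px tolerance, and a 40 px square
#' orientation window.
#'
#' @param threshold_level Integer grayscale cutoff in [0, 255]. Pixels with
#'   intensity strictly below this level are foreground (root), unless
#'   \code{invert_foreground} is set.
#' @param rdp_epsilon_px Distance tolerance (pixels) of the
#'   Ramer-Douglas-Peucker contour simplification used for edge smoothing.
#' @param angle_window_px Side (pixels) of the square neighborhood window
#'   over which per-pixel root orientation is estimated.
#' @param diameter_bin_edges Two ascending positive edges splitting root
#'   diameters into fine/medium/coarse classes. Interpreted in mm when
#'   \code{pixels_per_mm} is supplied, else in pixels.
#' @param pixels_per_mm Positive scale factor, or \code{NULL} to report all
#'   measures in pixel units.
#' @param save_segmented Write a per-image segmented (binary) PNG in batch mode.
#' @param save_feature_image Write a per-image feature-overlay PNG in batch mode.
#' @param invert_foreground If \code{TRUE}, foreground is bright
#'   (intensity >= \code{threshold_level}) instead of dark.
#'
#' @return An object of class \code{crown_config}.
#' @examples
#' cfg <- crown_config(pixels_per_mm = 13.63866)
#' cfg$diameter_bin_edges
#' @export
crown_config <- function(threshold_level = 128L,
                         rdp_epsilon_px = 2,
                         angle_window_px = 40L,
                         diameter_bin_edges = NULL,
                         pixels_per_mm = NULL,
                         save_segmented = FALSE,
                         save_feature_image = FALSE,
                         invert_foreground = FALSE) {
  threshold_level <- as.integer(threshold_level)
  if (is.na(threshold_level) || threshold_level < 0L || threshold_level > 255L)
    stop("`threshold_level` must be an integer in [0, 255]", call. = FALSE)
  if (!is.numeric(rdp_epsilon_px) || rdp_epsilon_px <= 0)
    stop("`rdp_epsilon_px` must be positive", call. = FALSE)
  angle_window_px <- as.integer(angle_window_px)
  if (is.na(angle_window_px) || angle_window_px < 3L)
    stop("`angle_window_px` must be an integer >= 3", call. = FALSE)
  if (!is.null(pixels_per_mm)) {
    if (!is.numeric(pixels_per_mm) || length(pixels_per_mm) != 1L ||
        !is.finite(pixels_per_mm) || pixels_per_mm <= 0)
      stop("`pixels_per_mm` must be a positive number", call. = FALSE)
  }
  if (is.null(diameter_bin_edges)) {
    # default classes: < 2 mm fine, 2-5 mm medium, > 5 mm coarse
    # (pixel-unit fallback uses the same numbers scaled at ~13.6 px/mm)
    diameter_bin_edges <- if (is.null(pixels_per_mm)) c(27, 68) else c(2, 5)
  }
  if (length(diameter_bin_edges) != 2L || any(diameter_bin_edges <= 0) ||
      diff(diameter_bin_edges) <= 0)
    stop("`diameter_bin_edges` must be two ascending positive values",
         call. = FALSE)
  structure(list(
    threshold_level = threshold_level,
    rdp_epsilon_px = as.numeric(rdp_epsilon_px),
    angle_window_px = angle_window_px,
    diameter_bin_edges = as.numeric(diameter_bin_edges),
    pixels_per_mm = if (is.null(pixels_per_mm)) NULL else as.numeric(pixels_per_mm),
    save_segmented = isTRUE(save_segmented),
    save_feature_image = isTRUE(save_feature_image),
    invert_foreground = isTRUE(invert_foreground)
  ), class = "crown_config")
}

#' @export
print.crown_config <- function(x, ...) {
  cat("Root crown analysis configuration\n")
  cat("  threshold_level:     ", x$threshold_level, "\n")
  cat("  rdp_epsilon_px:      ", x$rdp_epsilon_px, "\n")
  cat("  angle_window_px:     ", x$angle_window_px, "\n")
  cat("  diameter_bin_edges:  ", paste(x$diameter_bin_edges, collapse = ", "),
      if (is.null(x$pixels_per_mm)) " (px)" else " (mm)", "\n", sep = "")
  cat("  pixels_per_mm:       ",
      if (is.null(x$pixels_per_mm)) "not set (pixel units)" else x$pixels_per_mm,
      "\n")
  cat("  invert_foreground:   ", x$invert_foreground, "\n")
  invisible(x)
}

# canonical order of the 27 per-image phenes
feature_names <- function() {
  c("median_number_of_roots", "maximum_number_of_roots",
    "number_of_root_tips", "total_root_length", "depth", "maximum_width",
    "width_to_depth_ratio", "network_area", "convex_area", "solidity",
    "perimeter", "average_diameter", "median_diameter", "maximum_diameter",
    "volume", "surface_area", "lower_root_area", "holes",
    "average_hole_size", "average_root_orientation",
    "fine_diameter_frequency", "medium_diameter_frequency",
    "coarse_diameter_frequency", "shallow_angle_frequency",
    "medium_angle_frequency", "steep_angle_frequency", "computational_time")
}

# dimension classes used by unit conversion
.length_features <- c("total_root_length", "depth", "maximum_width",
                      "perimeter", "average_diameter", "median_diameter",
                      "maximum_diameter")
.area_features <- c("network_area", "convex_area", "lower_root_area",
                    "average_hole_size", "surface_area")
.volume_features <- "volume"

#' Construct a feature set row
#'
#' Internal constructor: a one-row data frame holding the 27 phenes plus the
#' image file name and a units flag.
#' @noRd
new_feature_set <- function(values, file_name = NA_character_, units = "px") {
  stopifnot(setequal(names(values), feature_names()))
  df <- as.data.frame(as.list(values[feature_names()]))
  df <- cbind(data.frame(file_name = file_name, stringsAsFactors = FALSE), df)
  attr(df, "units") <- units
  class(df) <- c("crown_features", "data.frame")
  df
}

#' Convert a pixel-unit feature set to physical units
#'
#' Divides length-like phenes by the scale, area-like phenes by its square
#' and volume by its cube; dimensionless phenes (counts, ratios, frequencies,
#' orientation) and the computational time are unchanged.
#'
#' @param features_px A \code{crown_features} row in pixel units, as returned
#'   by \code{\link{analyze_image}}.
#' @param pixels_per_mm Positive pixels-per-millimeter scale.
#' @return The feature set in mm / mm^2 / mm^3 units.
#' @examples
#' \dontrun{
#' feats_mm <- convert_units(feats_px, pixels_per_mm = 13.63866)
#' }
#' @export
convert_units <- function(features_px, pixels_per_mm) {
  if (!is.numeric(pixels_per_mm) || length(pixels_per_mm) != 1L ||
      !is.finite(pixels_per_mm) || pixels_per_mm <= 0)
    stop("`pixels_per_mm` must be a positive number", call. = FALSE)
  if (!identical(attr(features_px, "units"), "px"))
    stop("`features_px` must be in pixel units", call. = FALSE)
  out <- features_px
  out[.length_features] <- features_px[.length_features] / pixels_per_mm
  out[.area_features]   <- features_px[.area_features] / pixels_per_mm^2
  out[.volume_features] <- features_px[.volume_features] / pixels_per_mm^3
  attr(out, "units") <- "mm"
  out
}

#' @export
print.crown_features <- function(x, ...) {
  cat("Root crown features (", attr(x, "units"), " units) for ",
      x$file_name[1L], "\n", sep = "")
  v <- unlist(x[1L, feature_names()])
  for (nm in feature_names())
    cat(sprintf("  %-28s %g\n", nm, v[[nm]]))
  invisible(x)
}
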
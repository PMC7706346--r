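# Batch driver: analyze a folder of silhouettes, write CSV outputs.

#' Batch-process a folder of root crown images
#'
#' Analyzes every supported image (.png, .bmp, .jpg, .jpeg, .tif, .tiff) in
#' \code{input_dir} in lexicographic order and writes \code{features.csv}
#' (one row per image, the 27 phenes plus the file name) and
#' \code{metadata.csv} (key,value rows of all configuration fields) to
#' \code{output_dir}. Optionally writes per-image segmented
#' (\code{<name>_seg.png}) and feature-overlay (\code{<name>_features.png})
#' renders. A failing image is recorded with an error marker row and never
#' aborts the batch.
#'
#' @param input_dir Folder of input images.
#' @param output_dir Folder for outputs (created if missing).
#' @param config A \code{\link{crown_config}}.
#' @param seed Integer key for the deterministic hole colors of the
#'   feature-overlay renders.
#' @param log_file Optional path; timestamped one-line-per-image log.
#' @param verbose Print progress lines.
#' @return A \code{crown_batch} result: \code{features} (data frame with
#'   one row per input image; failed images carry NA features),
#'   \code{failures} (file, reason), and the output paths.
#' @export
run_batch <- function(input_dir, output_dir, config = crown_config(),
                      seed = 1L, log_file = NULL, verbose = FALSE) {
  if (!dir.exists(input_dir)) stop("input_dir does not exist", call. = FALSE)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  files <- sort(list.files(input_dir,
                           pattern = "\\.(png|bmp|jpg|jpeg|tif|tiff)$",
                           ignore.case = TRUE))
  logf <- function(msg) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "  ", msg)
    if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE)
    if (verbose) message(line)
  }
  rows <- list()
  failures <- data.frame(file = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  for (f in files) {
    res <- tryCatch({
      img <- read_gray_image(file.path(input_dir, f))
      ana <- analyze_image(img, config, file_name = f)
      if (config$save_segmented)
        png::writePNG(render_segmented(ana$mask),
                      file.path(output_dir, paste0(strip_ext(f), "_seg.png")))
      if (config$save_feature_image)
        png::writePNG(render_feature_image(ana$mask, ana$dmap, ana$skeleton,
                                           ana$topology, ana$hull,
                                           contours = ana$contours,
                                           seed = seed),
                      file.path(output_dir,
                                paste0(strip_ext(f), "_features.png")))
      logf(paste0("processed ", f))
      ana$features
    }, error = function(e) {
      logf(paste0("FAILED ", f, ": ", conditionMessage(e)))
      failures[nrow(failures) + 1L, ] <<- list(f, conditionMessage(e))
      err <- as.data.frame(as.list(stats::setNames(
        rep(NA_real_, length(feature_names())), feature_names())))
      cbind(data.frame(file_name = f, stringsAsFactors = FALSE), err)
    })
    rows[[length(rows) + 1L]] <- as.data.frame(res)
  }
  feats <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    empty <- as.data.frame(matrix(numeric(0), nrow = 0,
                                  ncol = length(feature_names()) + 1L))
    names(empty) <- c("file_name", feature_names())
    empty
  }
  features_path <- file.path(output_dir, "features.csv")
  metadata_path <- file.path(output_dir, "metadata.csv")
  utils::write.csv(feats, features_path, row.names = FALSE)
  write_metadata_csv(config, metadata_path)
  structure(list(features = feats, failures = failures,
                 features_path = features_path,
                 metadata_path = metadata_path,
                 n_input = length(files)),
            class = "crown_batch")
}

strip_ext <- function(f) sub("\\.[^.]+$", "", f)

#' @export
print.crown_batch <- function(x, ...) {
  cat("Batch result: ", x$n_input, " images, ",
      nrow(x$failures), " failures\n", sep = "")
  cat("  features: ", x$features_path, "\n", sep = "")
  invisible(x)
}

# metadata.csv: key,value rows of all configuration fields
write_metadata_csv <- function(config, path) {
  fields <- list(
    threshold_level = config$threshold_level,
    rdp_epsilon_px = config$rdp_epsilon_px,
    angle_window_px = config$angle_window_px,
    diameter_bin_edge_1 = config$diameter_bin_edges[1L],
    diameter_bin_edge_2 = config$diameter_bin_edges[2L],
    pixels_per_mm = if (is.null(config$pixels_per_mm)) "" else config$pixels_per_mm,
    units = if (is.null(config$pixels_per_mm)) "px" else "mm",
    save_segmented = config$save_segmented,
    save_feature_image = config$save_feature_image,
    invert_foreground = config$invert_foreground)
  df <- data.frame(key = names(fields),
                   value = vapply(fields, function(v) as.character(v), ""),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
}
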
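# File formats: raster images in (PNG/TIFF/JPEG via EBImage), PNG label
# masks, JSON sidecar metadata, YAML configuration, CSV collated metrics.
# All format dialect decisions live here.

MASK_LEVELS <- c(background = 0L, artery = 1L, vein = 2L, crossing = 3L, disc = 4L)

#' Construct an SLO image object
#'
#' @param pixels numeric matrix `[row, col]` of grayscale intensities
#'   (finite, non-negative).
#' @param scale_um_per_px optional isotropic spatial sampling scale in
#'   microns per pixel; when `NA` all downstream lengths/areas are reported
#'   in pixel units only.
#' @param laterality one of `"right"`, `"left"`, `"unknown"`.
#' @param location one of `"macula"`, `"disc"`, `"unknown"`.
#' @param image_id identifier used in output tables.
#' @return an object of class `slo_image`.
#' @export
slo_image <- function(pixels, scale_um_per_px = NA_real_,
                      laterality = "unknown", location = "unknown",
                      image_id = "image") {
  stopifnot(is.matrix(pixels))
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop("image pixels must be finite and non-negative")
  laterality <- match.arg(laterality, c("right", "left", "unknown"))
  location <- match.arg(location, c("macula", "disc", "unknown"))
  if (!is.na(scale_um_per_px) && scale_um_per_px <= 0)
    stop("scale_um_per_px must be positive")
  structure(
    list(pixels = pixels,
         height_px = nrow(pixels), width_px = ncol(pixels),
         scale_um_per_px = as.numeric(scale_um_per_px),
         laterality = laterality, location = location,
         image_id = as.character(image_id)),
    class = "slo_image")
}

#' @export
print.slo_image <- function(x, ...) {
  cat(sprintf("<slo_image> %s: %d x %d px, scale %s, %s eye, %s-centered\n",
              x$image_id, x$height_px, x$width_px,
              ifelse(is.na(x$scale_um_per_px), "unknown",
                     sprintf("%.2f um/px", x$scale_um_per_px)),
              x$laterality, x$location))
  invisible(x)
}

#' Read an SLO image with optional sidecar metadata
#'
#' Reads a PNG/TIFF/JPEG raster; multi-channel inputs are collapsed to
#' grayscale by the channel mean. Acquisition metadata (microns-per-pixel
#' scale, laterality, location) is read from a JSON sidecar named
#' `<image stem>.json` next to the image if present; explicit
#' `metadata_overrides` take precedence over sidecar values; anything absent
#' stays unknown rather than being guessed.
#'
#' @param path path to the image file.
#' @param metadata_overrides named list with any of `scale_um_per_px`,
#'   `laterality`, `location`, `image_id`.
#' @return an [slo_image()].
#' @export
read_slo_image <- function(path, metadata_overrides = list()) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("failed to decode image '", path,
                                           "': ", conditionMessage(e)))
  a <- as.array(img)
  if (length(dim(a)) == 3) a <- apply(a, c(1, 2), mean)
  if (length(dim(a)) != 2) stop("image '", path, "' is not 2-D after grayscale collapse")
  pixels <- t(a)
  meta <- list(scale_um_per_px = NA_real_, laterality = "unknown",
               location = "unknown",
               image_id = tools::file_path_sans_ext(basename(path)))
  sidecar <- file.path(dirname(path),
                       paste0(tools::file_path_sans_ext(basename(path)), ".json"))
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    for (k in intersect(names(meta), names(sc)))
      if (!is.null(sc[[k]]) && !all(is.na(sc[[k]]))) meta[[k]] <- sc[[k]]
  }
  for (k in intersect(names(meta), names(metadata_overrides)))
    if (!is.null(metadata_overrides[[k]])) meta[[k]] <- metadata_overrides[[k]]
  slo_image(pixels, scale_um_per_px = as.numeric(meta$scale_um_per_px),
            laterality = meta$laterality, location = meta$location,
            image_id = meta$image_id)
}

#' Write a sidecar metadata JSON for an image
#' @param image an [slo_image()].
#' @param path path of the JSON file to write.
#' @export
write_sidecar <- function(image, path) {
  .write_atomic(path, function(tmp) {
    jsonlite::write_json(
      list(image_id = image$image_id,
           scale_um_per_px = image$scale_um_per_px,
           laterality = image$laterality, location = image$location),
      tmp, auto_unbox = TRUE, digits = NA, na = "null")
  })
  invisible(path)
}

#' Write a label mask as an 8-bit PNG
#'
#' Encoding (fixed project-wide): 0 = background, 1 = artery, 2 = vein,
#' 3 = artery/vein crossing, 4 = optic disc. Binary masks (vessel, fovea)
#' use 0/1 under the same writer. Raw label values are stored in the PNG
#' (they look near-black in a viewer; scale on display).
#'
#' @param labels integer matrix of labels.
#' @param path output PNG path.
#' @export
write_mask <- function(labels, path) {
  stopifnot(is.matrix(labels))
  bad <- setdiff(unique(as.integer(labels)), unname(MASK_LEVELS))
  if (length(bad))
    stop("label values outside encoding {0,1,2,3,4}: ", paste(bad, collapse = ", "))
  .write_atomic(path, function(tmp) png::writePNG(labels / 255, tmp))
  invisible(path)
}

#' Read a label mask PNG
#'
#' @param path PNG path written by [write_mask()] (or any integer label PNG).
#' @param expected_shape optional `c(height, width)` to validate against.
#' @return integer matrix of labels.
#' @export
read_mask <- function(path, expected_shape = NULL) {
  if (!file.exists(path)) stop("cannot read mask: no such file: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  labels <- round(a * 255)
  labels <- matrix(labels, nrow(a), ncol(a))
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.integer(labels)), unname(MASK_LEVELS))
  if (length(bad))
    stop("mask '", path, "' has values outside encoding {0,1,2,3,4}: ",
         paste(sort(bad), collapse = ", "))
  if (!is.null(expected_shape) && !all(dim(labels) == expected_shape))
    stop("mask '", path, "' shape ", paste(dim(labels), collapse = "x"),
         " does not match expected ", paste(expected_shape, collapse = "x"))
  labels
}

# ---- collated metrics table -------------------------------------------------

METRICS_SCHEMA <- c(
  "image_id", "vessel_class", "roi", "laterality", "location",
  "scale_um_per_px", "fovea_x_px", "fovea_y_px", "disc_x_px", "disc_y_px",
  "disc_diameter_px", "n_segments",
  "vessel_density", "fractal_dimension",
  "global_caliber_px", "global_caliber_um",
  "local_caliber_px", "local_caliber_um",
  "tortuosity_density", "crae_px", "crae_um", "crve_px", "crve_um", "avr")

#' Write the collated metrics table
#'
#' One row per (image, vessel class, region of interest). Coordinates are
#' 0-based with `x = column`, `y = row`, origin top-left; `_px`/`_um`
#' suffixes state units in the header; micron columns are `NA` when no
#' spatial scale was available. Writing is atomic (temp file + rename).
#'
#' @param records tibble of metric records (rows of the schema produced by
#'   [compute_all_metrics()]).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_metrics_table <- function(records, path) {
  if (is.null(records) || nrow(records) == 0) {
    warning("no metric records; writing header-only table")
    records <- tibble::as_tibble(
      stats::setNames(rep(list(logical(0)), length(METRICS_SCHEMA)), METRICS_SCHEMA))
  }
  missing <- setdiff(METRICS_SCHEMA, names(records))
  if (length(missing))
    stop("metric records missing columns: ", paste(missing, collapse = ", "))
  records <- records[, METRICS_SCHEMA]
  .write_atomic(path, function(tmp) readr::write_csv(records, tmp, na = ""))
  invisible(path)
}

#' Read a collated metrics table
#' @param path CSV written by [write_metrics_table()].
#' @return a tibble.
#' @export
read_metrics_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    image_id = "c", vessel_class = "c", roi = "c",
                    laterality = "c", location = "c", .default = "d"))
}

# ---- configuration ----------------------------------------------------------

#' Default pipeline configuration
#'
#' All analysis parameters with their defaults. Keys use dotted names
#' (`postprocess.min_area_px`) in both the YAML file and this list.
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(
    input_dir = ".",
    output_dir = "slomorph_output",
    skip_on_error = FALSE,
    save_segmentations = TRUE,
    scale_um_per_px = NA_real_,
    laterality = NA_character_,
    location = NA_character_,
    `segmentation.threshold` = 0.5,
    `segmentation.scales_px` = c(1, 2, 4, 8),
    `postprocess.min_area_px` = 10,
    `postprocess.max_gap_px` = 3,
    `zones.boundary_rule` = "clip",      # or "midpoint"
    `zones.shape` = "circular",          # or "elliptical"
    `zones.exclude_disc_from_whole` = FALSE,
    `metrics.min_segment_len` = 10,
    `metrics.knudtson_n` = 6,
    `metrics.aggregation` = "length_weighted",  # or "mean"
    `metrics.fd_on_skeleton` = FALSE
  )
}

#' Read a pipeline configuration file
#'
#' YAML key-value file; nested maps are flattened to dotted keys.
#' Unspecified keys take the [default_config()] values; unknown keys raise
#' a warning (not an error).
#'
#' @param path YAML file path.
#' @return a `pipeline_config` (named list).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  parsed <- tryCatch(yaml::read_yaml(path),
                     error = function(e) stop("config parse error in '", path,
                                              "': ", conditionMessage(e)))
  flat <- .flatten_config(parsed)
  cfg <- default_config()
  unknown <- setdiff(names(flat), names(cfg))
  if (length(unknown))
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
  for (k in intersect(names(flat), names(cfg)))
    if (!is.null(flat[[k]])) cfg[[k]] <- flat[[k]]
  cfg$skip_on_error <- isTRUE(as.logical(cfg$skip_on_error))
  cfg$save_segmentations <- isTRUE(as.logical(cfg$save_segmentations))
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Write a pipeline configuration file
#' @param config named list of configuration values.
#' @param path YAML file path to write.
#' @export
write_config <- function(config, path) {
  .write_atomic(path, function(tmp)
    yaml::write_yaml(config[!vapply(config, function(x) all(is.na(x)), TRUE)], tmp))
  invisible(path)
}

.flatten_config <- function(x, prefix = "") {
  out <- list()
  for (k in names(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", k) else k
    if (is.list(x[[k]]) && !is.null(names(x[[k]]))) {
      out <- c(out, .flatten_config(x[[k]], key))
    } else {
      out[[key]] <- x[[k]]
    }
  }
  out
}

# atomic write: produce the file under a temp name in the target directory,
# then rename, so a killed batch never leaves a partial table
.write_atomic <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(pattern = paste0(".", basename(path), "."),
                  tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temp file onto ", path)
  invisible(path)
}
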
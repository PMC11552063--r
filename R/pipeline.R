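# End-to-end orchestration: per-image analysis, deterministic batch
# processing with error skipping, per-image process logs, segmentation
# visualization output, and the corrected-mask re-computation loop.

.log_new <- function(image_id) {
  env <- new.env(parent = emptyenv())
  env$image_id <- image_id
  env$messages <- character(0)
  env$warnings <- character(0)
  env$status <- "ok"
  env
}
.log_msg <- function(log, stage, msg) {
  log$messages <- c(log$messages,
                    sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
  invisible(log)
}
.log_finish <- function(log) {
  list(image_id = log$image_id, status = log$status,
       messages = log$messages, warnings = log$warnings)
}

# mask discovery for one image stem: manually corrected masks (saved next to
# the originals in the per-image output folder) take absolute precedence;
# externally supplied masks come from masks_dir; otherwise NULL and the
# baseline segmentation runs.
.discover_masks <- function(stem, masks_dir, image_out_dir) {
  kinds <- c("avod", "vessel", "fovea")
  paths <- list()
  for (k in kinds) {
    cand <- c(
      file.path(image_out_dir, sprintf("%s_%s_corrected.png", stem, k)),
      if (!is.null(masks_dir))
        file.path(masks_dir, sprintf("%s_%s_corrected.png", stem, k)),
      if (!is.null(masks_dir))
        file.path(masks_dir, sprintf("%s_%s.png", stem, k)))
    hit <- cand[file.exists(cand)]
    if (length(hit)) paths[[k]] <- hit[1]
  }
  if (length(paths)) paths else NULL
}

#' Analyse a single SLO image
#'
#' Full pipeline for one image: read (+ sidecar metadata and config
#' overrides) -> segmentation (ingest corrected/external masks when present,
#' else the classical baseline) -> post-processing -> landmark extraction ->
#' laterality/location inference (unless provided) -> region-of-interest
#' construction -> metric suite -> per-image outputs (metrics rows, process
#' log, metadata JSON, masks and an overlay visualization when
#' `save_segmentations` is on).
#'
#' @param image_path path to the image file.
#' @param config configuration list (see [default_config()]).
#' @param output_dir output root; per-image artifacts go to
#'   `<output_dir>/<image stem>/`.
#' @param masks_dir optional directory of externally supplied masks.
#' @param baseline force the classical baseline even if masks exist.
#' @return list with `records` (metrics tibble), `log`, `bundle`,
#'   `landmarks`, `paths`.
#' @export
run_single <- function(image_path, config = default_config(),
                       output_dir = config$output_dir, masks_dir = NULL,
                       baseline = FALSE) {
  stem <- tools::file_path_sans_ext(basename(image_path))
  log <- .log_new(stem)
  out_dir <- file.path(output_dir, stem)
  overrides <- list()
  if (!is.na(config$scale_um_per_px)) overrides$scale_um_per_px <- config$scale_um_per_px
  if (!is.na(config$laterality)) overrides$laterality <- config$laterality
  if (!is.na(config$location)) overrides$location <- config$location

  image <- read_slo_image(image_path, overrides)
  .log_msg(log, "read", sprintf("%dx%d px", image$height_px, image$width_px))

  withCallingHandlers({
    mask_paths <- if (!baseline) .discover_masks(stem, masks_dir, out_dir) else NULL
    bundle <- if (!is.null(mask_paths)) {
      b <- ingest_bundle(image, mask_paths)
      .log_msg(log, "segmentation",
               sprintf("ingested %s masks: %s", b$provenance,
                       paste(names(mask_paths), collapse = ", ")))
      b
    } else {
      b <- segment_baseline(image, config)
      .log_msg(log, "segmentation", "baseline vesselness path")
      b
    }

    fovea <- fovea_centroid(bundle$binary$fovea)
    disc <- fit_disc(bundle$binary$disc)
    .log_msg(log, "landmarks", sprintf(
      "fovea %s, disc %s",
      if (fovea$present) sprintf("(%.1f, %.1f)", fovea$x_px, fovea$y_px) else "absent",
      if (disc$present) sprintf("(%.1f, %.1f) D=%.1f", disc$x_px, disc$y_px,
                                disc$diameter_px) else "absent"))

    laterality <- image$laterality
    location <- image$location
    if (laterality == "unknown" || location == "unknown") {
      inferred <- suppressWarnings(
        infer_laterality_location(fovea, disc, dim(image$pixels)))
      if (laterality == "unknown") laterality <- inferred$laterality
      if (location == "unknown") location <- inferred$location
      .log_msg(log, "inference",
               sprintf("laterality=%s location=%s", laterality, location))
    }
    image$laterality <- laterality
    image$location <- location

    rois <- roi_set(location, disc, dim(image$pixels),
                    shape = config$`zones.shape`,
                    exclude_disc_from_whole = config$`zones.exclude_disc_from_whole`)
    records <- compute_all_metrics(bundle, rois, image, fovea, disc, config)
    .log_msg(log, "metrics", sprintf("%d records", nrow(records)))

    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metrics_table(records, file.path(out_dir, "metrics.csv"))
    .write_atomic(file.path(out_dir, "metadata.json"), function(tmp)
      jsonlite::write_json(list(
        image_id = image$image_id, laterality = laterality, location = location,
        scale_um_per_px = image$scale_um_per_px,
        fovea = fovea[c("x_px", "y_px", "present")],
        disc = disc[c("x_px", "y_px", "diameter_px", "present")],
        provenance = bundle$provenance),
        tmp, auto_unbox = TRUE, digits = NA, na = "null"))
    if (isTRUE(config$save_segmentations)) {
      labels <- matrix(0L, image$height_px, image$width_px)
      labels[bundle$binary$artery == 1L] <- 1L
      labels[bundle$binary$vein == 1L] <- 2L
      labels[bundle$binary$artery == 1L & bundle$binary$vein == 1L] <- 3L
      labels[bundle$binary$disc == 1L & labels == 0L] <- 4L
      if (bundle$provenance == "baseline") {
        write_mask(labels, file.path(out_dir, paste0(stem, "_avod.png")))
        write_mask(bundle$binary$vessel, file.path(out_dir, paste0(stem, "_vessel.png")))
        write_mask(bundle$binary$fovea, file.path(out_dir, paste0(stem, "_fovea.png")))
      }
      render_overlay(image, bundle, fovea, disc, rois,
                     file.path(out_dir, paste0(stem, "_overlay.png")))
      .log_msg(log, "output", "segmentations and overlay saved")
    }
    logout <- .log_finish(log)
    .write_atomic(file.path(out_dir, "log.txt"), function(tmp)
      writeLines(c(sprintf("image: %s", stem),
                   sprintf("status: %s", logout$status),
                   logout$messages, logout$warnings), tmp))
    list(records = records, log = logout, bundle = bundle,
         landmarks = list(fovea = fovea, disc = disc), paths = out_dir)
  }, warning = function(w) {
    log$warnings <- c(log$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
}

#' Analyse a batch of SLO images
#'
#' Processes every supported image in `input_dir` in deterministic
#' (lexicographic) order, collates all metric rows into
#' `<output_dir>/collated_metrics.csv` (written atomically), and returns
#' per-image logs and ok/skipped/failed counts. With
#' `config$skip_on_error = TRUE`, failing images are skipped and the batch
#' continues; otherwise the first failure aborts.
#'
#' @param input_dir directory containing images (mask/sidecar companions of
#'   synthetic scenes are recognized and not analysed as images).
#' @param config configuration list.
#' @param output_dir output root.
#' @param masks_dir optional directory of externally supplied masks.
#' @param baseline force the classical baseline path.
#' @return list with `table` (collated tibble), `logs`, `summary`,
#'   `table_path`.
#' @export
run_batch <- function(input_dir, config = default_config(),
                      output_dir = config$output_dir, masks_dir = NULL,
                      baseline = FALSE) {
  files <- list.files(input_dir, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                      ignore.case = TRUE, full.names = TRUE)
  files <- files[!grepl("_(avod|vessel|fovea|overlay)(_corrected)?\\.png$",
                        basename(files), ignore.case = TRUE)]
  files <- files[order(basename(files), method = "radix")]
  if (length(files) == 0) stop("no supported images found in ", input_dir)
  logs <- list()
  tables <- list()
  status <- character(0)
  for (f in files) {
    res <- tryCatch(
      run_single(f, config, output_dir = output_dir, masks_dir = masks_dir,
                 baseline = baseline),
      error = function(e) e)
    if (inherits(res, "error")) {
      if (!config$skip_on_error)
        stop("processing failed for '", basename(f), "': ",
             conditionMessage(res))
      logs[[length(logs) + 1L]] <- list(
        image_id = tools::file_path_sans_ext(basename(f)),
        status = "skipped", messages = character(0),
        warnings = conditionMessage(res))
      status <- c(status, "skipped")
      next
    }
    logs[[length(logs) + 1L]] <- res$log
    tables[[length(tables) + 1L]] <- res$records
    status <- c(status, res$log$status)
  }
  table <- dplyr::bind_rows(tables)
  table_path <- file.path(output_dir, "collated_metrics.csv")
  write_metrics_table(table, table_path)
  list(table = table, logs = logs,
       summary = c(ok = sum(status == "ok"), skipped = sum(status == "skipped"),
                   failed = sum(status == "failed")),
       table_path = table_path)
}

#' Render a segmentation overlay figure
#'
#' Superimposes the segmentation on the SLO image for quality checking:
#' arteries red, veins blue, crossings magenta, unclassified vessels
#' orange, disc outline yellow, fovea marker green, and (for disc-centered
#' scans) white zone-boundary rings at radii {0.5D, 1D, 1.5D, 2.5D}.
#'
#' @param image an [slo_image()].
#' @param bundle an `slo_bundle`.
#' @param fovea,disc landmark results.
#' @param rois named ROI list (zone rings are drawn iff zones are present).
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
render_overlay <- function(image, bundle, fovea, disc, rois, path) {
  g <- image$pixels / max(image$pixels, 1e-9)
  rgb <- array(rep(g, 3), dim = c(dim(g), 3))
  paint <- function(rgb, mask, col, alpha = 0.6) {
    cc <- col2rgb(col)[, 1] / 255
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[mask] <- (1 - alpha) * plane[mask] + alpha * cc[ch]
      rgb[, , ch] <- plane
    }
    rgb
  }
  vu <- bundle$binary$vessel == 1L & bundle$binary$artery == 0L &
    bundle$binary$vein == 0L
  rgb <- paint(rgb, vu, "orange")
  rgb <- paint(rgb, bundle$binary$artery == 1L & bundle$binary$vein == 0L, "red")
  rgb <- paint(rgb, bundle$binary$vein == 1L & bundle$binary$artery == 0L, "blue")
  rgb <- paint(rgb, bundle$binary$artery == 1L & bundle$binary$vein == 1L, "magenta")
  if (isTRUE(disc$present)) {
    r <- .radius_field(nrow(g), ncol(g), disc$y_px, disc$x_px)
    ring <- abs(r - disc$diameter_px / 2) <= 1
    rgb <- paint(rgb, ring, "yellow", alpha = 1)
    if (!is.null(rois$zoneB)) {
      for (mult in c(0.5, 1, 1.5, 2.5))
        rgb <- paint(rgb, abs(r - mult * disc$diameter_px) <= 0.75, "white",
                     alpha = 0.8)
    }
  }
  if (isTRUE(fovea$present)) {
    r <- .radius_field(nrow(g), ncol(g), fovea$y_px, fovea$x_px)
    rgb <- paint(rgb, r <= 4, "green", alpha = 1)
  }
  .write_atomic(path, function(tmp) png::writePNG(rgb, tmp))
  invisible(path)
}
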
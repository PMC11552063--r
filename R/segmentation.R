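# Segmentation bundles: either ingested external/corrected masks (the
# primary correction workflow) or a classical multiscale vesselness baseline
# standing in for trained networks, so the measurement module is exercisable
# end to end. Analysis happens at a 768 x 768 working resolution; probability
# maps are resized back to native resolution before thresholding.

WORKING_RESOLUTION <- c(768L, 768L)

#' Resize an image or map to/from the working resolution
#'
#' Intensity and probability rasters are resized with bilinear
#' interpolation; label/binary rasters with nearest neighbour so no new
#' label values appear.
#'
#' @param m matrix.
#' @param target `c(height, width)` (default 768 x 768).
#' @param kind `"intensity"`, `"probability"` or `"label"`.
#' @return resized matrix.
#' @export
resize_to_working <- function(m, target = WORKING_RESOLUTION,
                              kind = c("intensity", "probability", "label")) {
  kind <- match.arg(kind)
  if (any(target <= 0)) stop("target resolution must be positive")
  if (all(dim(m) == target)) return(m)
  filt <- if (kind == "label") "none" else "bilinear"
  out <- .from_eb(EBImage::resize(.as_eb(m), w = target[2], h = target[1],
                                  filter = filt))
  if (kind == "label") storage.mode(out) <- "integer"
  if (kind == "probability") out <- pmin(pmax(out, 0), 1)
  out
}

#' Multiscale vesselness (Hessian ridge filter)
#'
#' Frangi-style vesselness for bright curvilinear ridges on a darker
#' background: at each scale the image is Gaussian-smoothed (sigma = half
#' the target ridge width), the scale-normalized Hessian eigenvalues
#' (|l1| <= |l2|) are computed, and pixels with strongly negative l2 score
#'   `exp(-(l1/l2)^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))`
#' with `S = sqrt(l1^2 + l2^2)` and `c` set to half the maximum `S` of the
#' scale. The response is the maximum over scales, rescaled to [0, 1].
#' A constant image yields an all-zero map.
#'
#' @param image grayscale matrix (working resolution).
#' @param scales_px ridge widths to respond to, in pixels.
#' @param beta blobness sensitivity.
#' @return probability-like matrix in [0, 1].
#' @export
vesselness <- function(image, scales_px = c(1, 2, 4, 8), beta = 0.5) {
  stopifnot(is.matrix(image))
  k_rr <- matrix(c(0, 1, 0, 0, -2, 0, 0, 1, 0), 3, 3)
  k_cc <- t(k_rr)
  k_rc <- matrix(c(1, 0, -1, 0, 0, 0, -1, 0, 1), 3, 3) / 4
  best <- matrix(0, nrow(image), ncol(image))
  for (w in scales_px) {
    sigma <- max(w / 2, 0.5)
    sm <- .gauss_blur(image, sigma)
    hrr <- .filter2c(sm, k_rr) * sigma^2
    hcc <- .filter2c(sm, k_cc) * sigma^2
    hrc <- .filter2c(sm, k_rc) * sigma^2
    tr2 <- (hrr + hcc) / 2
    det_rt <- sqrt(pmax(((hrr - hcc) / 2)^2 + hrc^2, 0))
    e1 <- tr2 + det_rt
    e2 <- tr2 - det_rt
    # order by magnitude: |l1| <= |l2|
    swap <- abs(e1) > abs(e2)
    l1 <- ifelse(swap, e2, e1)
    l2 <- ifelse(swap, e1, e2)
    S2 <- l1^2 + l2^2
    c2 <- max(S2) / 4  # (max(S)/2)^2
    v <- matrix(0, nrow(image), ncol(image))
    ok <- l2 < 0 & abs(l2) > 1e-12
    if (any(ok) && c2 > 0) {
      rb2 <- (l1[ok] / l2[ok])^2
      v[ok] <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-S2[ok] / (2 * c2)))
    }
    best <- pmax(best, v)
  }
  m <- max(best)
  if (m > 0) best <- best / m
  best
}

# Gaussian blur and linear filtering with circular boundary (exactly
# 90-degree-rotation equivariant on square canvases)
.gauss_blur <- function(m, sigma) {
  matrix(as.numeric(EBImage::gblur(m, sigma = sigma)), nrow(m), ncol(m))
}
.filter2c <- function(m, k) {
  matrix(as.numeric(EBImage::filter2(m, k, boundary = "circular")),
         nrow(m), ncol(m))
}

#' Vessel probability map for the baseline segmenter
#'
#' Converts the peaked ridge response of [vesselness()] into a saturated,
#' full-width probability map of the kind a trained vessel segmenter emits.
#' Ridge crests (the upper half of the max-normalized ridge response)
#' define where vessels run; a white top-hat of the image
#' (disc structuring element wider than the largest expected vessel)
#' provides the cross-sectional intensity evidence, which is normalized by
#' half the median top-hat value over the ridge cores — the half-maximum of
#' a smooth bright vessel profile — and clipped to [0, 1], so the map
#' saturates across most of the vessel width while staying zero off the
#' dilated ridge support.
#'
#' @param image grayscale matrix at working resolution.
#' @param scales_px ridge widths for [vesselness()].
#' @param beta blobness sensitivity for [vesselness()].
#' @param tophat_diameter_px structuring-element diameter.
#' @return probability matrix in [0, 1].
#' @export
vessel_probability <- function(image, scales_px = c(1, 2, 4, 8), beta = 0.5,
                               tophat_diameter_px = 17) {
  v <- vesselness(image, scales_px = scales_px, beta = beta)
  core <- (v >= 0.5) * 1L  # ridge crest: upper half of the (max-normalized) response
  if (!any(core > 0L)) return(v * 0)
  support <- .from_eb(EBImage::dilate(
    .as_eb(core), EBImage::makeBrush(15, shape = "disc"))) > 0
  th <- .from_eb(EBImage::whiteTopHat(
    .as_eb(image), EBImage::makeBrush(tophat_diameter_px, shape = "disc")))
  ref <- stats::median(th[core == 1L])
  p <- if (ref > 0) pmin(pmax(th, 0) / (0.5 * ref), 1) else th * 0
  pmax(p, v) * support
}

#' Baseline fovea detection
#'
#' The foveal pit appears as a dark spot: the map peaks at the darkest
#' smoothed local minimum within the central half of the image and is
#' shaped as a disc of radius 60 px around it (the same geometry as a
#' fovea training label). The peak value encodes confidence (depth of the
#' dip relative to the central background); maps from images without a
#' discernible dip stay below the 0.5 binarization threshold so the fovea
#' is reported absent. Ties between equally dark minima break to the
#' leftmost (then topmost) pixel.
#'
#' @param image grayscale matrix.
#' @param sigma_px smoothing scale.
#' @param depth_ref dip depth (intensity units) that maps to confidence 1.
#' @return probability matrix in [0, 1].
#' @export
detect_fovea_baseline <- function(image, sigma_px = 15, depth_ref = 0.06) {
  sm <- .gauss_blur(image, sigma_px)
  nr <- nrow(sm); nc <- ncol(sm)
  rs <- (floor(nr / 4) + 1L):ceiling(3 * nr / 4)
  cs <- (floor(nc / 4) + 1L):ceiling(3 * nc / 4)
  central <- sm[rs, cs]
  mn <- min(central)
  hits <- which(central == mn, arr.ind = TRUE)
  hits <- hits[order(hits[, 2], hits[, 1]), , drop = FALSE]  # leftmost, then topmost
  r0 <- rs[hits[1, 1]]; c0 <- cs[hits[1, 2]]
  depth <- stats::median(central) - mn
  conf <- min(1, max(0, depth / depth_ref))
  map <- matrix(0, nr, nc)
  disc <- .radius_field(nr, nc, r0 - 1, c0 - 1) <= 60
  map[disc] <- conf
  map
}

#' Baseline optic-disc detection
#'
#' The optic disc is the large bright smooth region: the image is smoothed
#' at a scale that suppresses vessels, thresholded above the median by
#' `min_contrast`, morphologically opened, and the largest 8-connected
#' component is kept if it is plausibly disc-sized.
#'
#' @param image grayscale matrix.
#' @param sigma_px smoothing scale.
#' @param min_contrast threshold above the median smoothed intensity.
#' @param min_area_px minimum accepted component area.
#' @return probability matrix in [0, 1] (1 inside the detected disc).
#' @export
detect_disc_baseline <- function(image, sigma_px = 8, min_contrast = 0.15,
                                 min_area_px = 2000) {
  sm <- .gauss_blur(image, sigma_px)
  cand <- (sm >= stats::median(sm) + min_contrast) * 1L
  if (any(cand > 0L)) {
    brush <- EBImage::makeBrush(11, shape = "disc")
    cand <- .from_eb(EBImage::opening(.as_eb(cand), brush))
    storage.mode(cand) <- "integer"
  }
  out <- matrix(0, nrow(image), ncol(image))
  if (!any(cand > 0L)) return(out)
  lab <- label_components8(cand)
  areas <- tabulate(lab[lab > 0L])
  if (max(areas) < min_area_px) return(out)
  out[lab == which.max(areas)] <- 1
  out
}

# heuristic artery/vein split for baseline segmentation: vessels are grouped
# into 8-connected components and split at the midpoint of the component
# mean-intensity range (arteries are rendered/appear dimmer than veins);
# skipped when the intensity contrast between components is too small to
# separate, and only meaningful on scenes where the classes are not merged
# by arteriovenous crossings.
.split_arteries_veins <- function(image, vessel_mask, min_contrast = 0.02) {
  lab <- label_components8(vessel_mask)
  ncomp <- max(lab)
  artery <- matrix(0L, nrow(vessel_mask), ncol(vessel_mask))
  vein <- matrix(0L, nrow(vessel_mask), ncol(vessel_mask))
  if (ncomp < 2) return(list(artery = artery, vein = vein))
  means <- vapply(seq_len(ncomp), function(k) mean(image[lab == k]), 0)
  if (diff(range(means)) < min_contrast)
    return(list(artery = artery, vein = vein))
  thr <- mean(range(means))
  for (k in seq_len(ncomp)) {
    if (means[k] < thr) artery[lab == k] <- 1L else vein[lab == k] <- 1L
  }
  list(artery = artery, vein = vein)
}

.new_bundle <- function(prob, binary, native_resolution, provenance) {
  structure(list(prob = prob, binary = binary,
                 working_resolution = WORKING_RESOLUTION,
                 native_resolution = native_resolution,
                 provenance = provenance),
            class = "slo_bundle")
}

#' @export
print.slo_bundle <- function(x, ...) {
  cat(sprintf("<slo_bundle> %s, native %dx%d; maps: %s\n", x$provenance,
              x$native_resolution[1], x$native_resolution[2],
              paste(names(x$binary), collapse = ", ")))
  invisible(x)
}

#' Baseline segmentation of an SLO image
#'
#' Classical pipeline: resize to the 768 x 768 working resolution, run the
#' multiscale vesselness filter plus the baseline fovea and disc detectors,
#' resize all probability maps back to native resolution, threshold at 0.5,
#' then post-process the binary vessel map (small-component removal and gap
#' bridging, with pixel parameters scaled to native resolution). Fully
#' deterministic: the same image always yields the same bundle.
#'
#' @param image an [slo_image()].
#' @param config parameter list (see [default_config()]).
#' @param av_split attempt the heuristic artery/vein split.
#' @return an `slo_bundle`.
#' @export
segment_baseline <- function(image, config = default_config(), av_split = TRUE) {
  native <- dim(image$pixels)
  work <- resize_to_working(image$pixels, kind = "intensity")
  prob_w <- list(
    vessel = vessel_probability(work, scales_px = config$`segmentation.scales_px`),
    fovea = detect_fovea_baseline(work),
    disc = detect_disc_baseline(work))
  prob <- lapply(prob_w, resize_to_working, target = native, kind = "probability")
  thr <- config$`segmentation.threshold`
  scale2 <- prod(native) / prod(WORKING_RESOLUTION)
  vessel <- binarize(prob$vessel, thr)
  vessel <- clean_mask(vessel, config$`postprocess.min_area_px` * scale2)
  vessel <- bridge_gaps(vessel, config$`postprocess.max_gap_px` * sqrt(scale2))
  disc <- binarize(prob$disc, thr)
  if (any(disc > 0L)) {
    lab <- label_components8(disc)
    disc <- (lab == which.max(tabulate(lab[lab > 0L]))) * 1L
  }
  fovea <- binarize(prob$fovea, thr)
  av <- if (av_split) .split_arteries_veins(image$pixels, vessel)
        else list(artery = matrix(0L, native[1], native[2]),
                  vein = matrix(0L, native[1], native[2]))
  prob$artery <- av$artery * prob$vessel
  prob$vein <- av$vein * prob$vessel
  .new_bundle(prob,
              list(vessel = vessel, artery = av$artery, vein = av$vein,
                   disc = disc, fovea = fovea),
              native, "baseline")
}

#' Ingest external or manually corrected masks
#'
#' Builds a segmentation bundle from saved mask files; corrected masks take
#' absolute precedence over anything computed. `mask_paths` is a named list
#' with any of:
#' * `avod` — label mask (1 = artery, 2 = vein, 3 = crossing, 4 = disc),
#' * `vessel` — binary all-vessel mask,
#' * `fovea` — binary fovea mask.
#' The all-vessel mask is recomputed as artery U vein U crossing when only
#' an `avod` mask is supplied. Provenance is `"corrected"` when any path
#' contains the `_corrected` suffix, else `"external"`.
#'
#' @param image an [slo_image()].
#' @param mask_paths named list of file paths.
#' @return an `slo_bundle`.
#' @export
ingest_bundle <- function(image, mask_paths) {
  shape <- dim(image$pixels)
  if (length(mask_paths) == 0) stop("no masks supplied to ingest")
  zero <- matrix(0L, shape[1], shape[2])
  artery <- vein <- disc <- fovea <- zero
  vessel <- NULL
  if (!is.null(mask_paths$avod)) {
    lab <- read_mask(mask_paths$avod, expected_shape = shape)
    artery <- (lab == 1L | lab == 3L) * 1L
    vein <- (lab == 2L | lab == 3L) * 1L
    disc <- (lab == 4L) * 1L
  }
  if (!is.null(mask_paths$vessel))
    vessel <- .as_binary(read_mask(mask_paths$vessel, expected_shape = shape))
  if (is.null(vessel)) vessel <- .as_binary(artery | vein)
  if (!is.null(mask_paths$fovea))
    fovea <- .as_binary(read_mask(mask_paths$fovea, expected_shape = shape))
  # harmonize: classified vessels are vessels
  vessel <- .as_binary(vessel | artery | vein)
  binary <- list(vessel = vessel, artery = artery, vein = vein,
                 disc = disc, fovea = fovea)
  provenance <- if (any(grepl("_corrected", unlist(mask_paths), fixed = TRUE)))
    "corrected" else "external"
  .new_bundle(lapply(binary, function(b) b * 1), binary, shape, provenance)
}
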
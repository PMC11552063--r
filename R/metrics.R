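# The measurement module: vessel segment decomposition and the vascular
# metric suite — vessel density, box-counting fractal dimension, global and
# local caliber, Grisan tortuosity density, Knudtson CRAE/CRVE and the
# arteriole-to-venule ratio — per vessel class and region of interest.

# ordered simple paths of a skeleton after removing junction pixels
# (junction = skeleton pixel with >= 3 distinct skeleton branches)
.skeleton_paths <- function(skeleton) {
  s <- .as_binary(skeleton)
  if (!any(s > 0L)) return(list())
  branches <- count_branches8(s)
  path_mask <- s
  path_mask[branches >= 3L] <- 0L
  lab <- label_components8(path_mask)
  n <- max(lab)
  if (n == 0L) return(list())
  pts_all <- which(lab > 0L, arr.ind = TRUE)
  lapply(seq_len(n), function(k) {
    .trace_path(pts_all[lab[pts_all] == k, , drop = FALSE])
  })
}

#' Decompose a skeleton into vessel segments
#'
#' Junction pixels (three or more distinct skeleton branches meeting under
#' 8-connectivity — vessel bifurcations and arteriovenous crossings) are
#' removed, splitting the
#' skeleton into simple paths; each path is traced in order and paths with
#' arc length below `min_segment_len` are discarded. Arc length counts 1
#' per axial step and sqrt(2) per diagonal step; the chord is the Euclidean
#' endpoint distance.
#'
#' @param skeleton binary skeleton matrix (see [skeletonize()]).
#' @param mask optional vessel mask used for per-point caliber estimates.
#' @param min_segment_len minimum retained arc length in pixels.
#' @return list of `vessel_segment` objects (fields: `points` — ordered
#'   (row, col) 1-based matrix, `widths_px`, `arc_length_px`,
#'   `chord_length_px`, `mean_width_px`).
#' @export
decompose_segments <- function(skeleton, mask = NULL, min_segment_len = 10) {
  paths <- .skeleton_paths(skeleton)
  wmap <- if (!is.null(mask)) .width_map(mask, skeleton) else NULL
  out <- list()
  for (pts in paths) {
    if (nrow(pts) < 3) next
    arc <- .path_arc_length(pts)
    if (arc < min_segment_len) next
    widths <- if (is.null(wmap)) rep(NA_real_, nrow(pts)) else wmap[pts]
    out[[length(out) + 1L]] <- structure(
      list(points = pts, widths_px = widths,
           arc_length_px = arc, chord_length_px = .path_chord_length(pts),
           mean_width_px = mean(widths)),
      class = "vessel_segment")
  }
  out
}

#' Segment decomposition of a vessel mask
#'
#' Convenience wrapper: skeletonize the mask, estimate per-point widths from
#' the distance transform, and decompose into segments.
#'
#' @inheritParams decompose_segments
#' @param mask binary vessel mask.
#' @return list of `vessel_segment`s.
#' @export
vessel_segments <- function(mask, min_segment_len = 10) {
  decompose_segments(skeletonize(mask), mask = mask,
                     min_segment_len = min_segment_len)
}

#' Vessel density
#'
#' Ratio of vessel pixels to all pixels of the region of interest.
#'
#' @param mask binary vessel mask.
#' @param roi `roi_mask` (default: whole image).
#' @return fraction in [0, 1].
#' @export
vessel_density <- function(mask, roi = whole_image_roi(dim(mask))) {
  stopifnot(all(dim(mask) == dim(roi$mask)))
  if (roi$area_px == 0) return(NA_real_)
  sum(.as_binary(mask) & roi$mask) / roi$area_px
}

#' Box-counting (Minkowski-Bouligand) fractal dimension
#'
#' The mask is restricted to the bounding box of the ROI; grid sizes are
#' powers of 2 from 2 px up to a quarter of the shorter box side, anchored
#' at the bounding-box origin; N(s) counts occupied s x s cells and the
#' dimension is minus the least-squares slope of log N(s) against log s.
#' Returns `NA` (with a warning) when the mask is empty or fewer than three
#' grid sizes are available.
#'
#' @param mask binary vessel mask.
#' @param roi optional `roi_mask` restriction.
#' @param on_skeleton compute on the skeletonized mask instead of the
#'   full-thickness mask (the default is the full mask).
#' @return fractal dimension (dimensionless) or `NA`.
#' @export
fractal_dimension <- function(mask, roi = NULL, on_skeleton = FALSE) {
  b <- .as_binary(mask)
  if (!is.null(roi)) b <- restrict(b, roi)
  if (isTRUE(on_skeleton)) b <- skeletonize(b)
  pts <- which(b == 1L, arr.ind = TRUE)
  if (nrow(pts) == 0) {
    warning("fractal dimension undefined for an empty mask")
    return(NA_real_)
  }
  box <- if (is.null(roi)) {
    cbind(c(1L, nrow(b)), c(1L, ncol(b)))
  } else {
    rp <- which(roi$mask == 1L, arr.ind = TRUE)
    cbind(range(rp[, 1]), range(rp[, 2]))
  }
  short <- min(box[2, ] - box[1, ] + 1)
  sizes <- 2^(1:30)
  sizes <- sizes[sizes <= short / 4]
  if (length(sizes) < 3) {
    warning("fewer than 3 usable grid sizes; fractal dimension undefined")
    return(NA_real_)
  }
  r0 <- pts[, 1] - box[1, 1]
  c0 <- pts[, 2] - box[1, 2]
  counts <- vapply(sizes, function(s) {
    length(unique((r0 %/% s) * (max(c0 %/% s) + 1) + (c0 %/% s)))
  }, 0L)
  fit <- stats::lm(log(counts) ~ log(sizes))
  -unname(stats::coef(fit)[2])
}

#' Global vessel caliber
#'
#' Ratio of vessel pixels to skeletonized vessel pixels — the mean vessel
#' width over the whole map.
#'
#' @param mask binary vessel mask.
#' @param skeleton optional precomputed skeleton.
#' @param scale_um_per_px optional scale; when given the result is microns.
#' @return caliber in px (or microns if a scale is supplied); `NA` on an
#'   empty skeleton.
#' @export
global_caliber <- function(mask, skeleton = NULL, scale_um_per_px = NULL) {
  b <- .as_binary(mask)
  if (is.null(skeleton)) skeleton <- skeletonize(b)
  ns <- sum(skeleton > 0)
  if (ns == 0) return(NA_real_)
  out <- sum(b) / ns
  if (!is.null(scale_um_per_px) && !is.na(scale_um_per_px))
    out <- out * scale_um_per_px
  out
}

#' Local vessel caliber
#'
#' Per-point caliber along each segment comes from the Euclidean distance
#' transform of the vessel mask at the skeleton points (see
#' [decompose_segments()]); each segment contributes its mean width, and the
#' region value is the segment-arc-length-weighted mean (or the plain mean
#' with `aggregation = "mean"`).
#'
#' @param segments list of `vessel_segment`s.
#' @param scale_um_per_px optional scale for micron units.
#' @param aggregation `"length_weighted"` or `"mean"`.
#' @return caliber in px (or microns); `NA` if no segments.
#' @export
local_caliber <- function(segments, scale_um_per_px = NULL,
                          aggregation = c("length_weighted", "mean")) {
  aggregation <- match.arg(aggregation)
  if (length(segments) == 0) return(NA_real_)
  wbar <- vapply(segments, `[[`, 0, "mean_width_px")
  len <- vapply(segments, `[[`, 0, "arc_length_px")
  out <- if (aggregation == "length_weighted") sum(wbar * len) / sum(len)
         else mean(wbar)
  if (!is.null(scale_um_per_px) && !is.na(scale_um_per_px))
    out <- out * scale_um_per_px
  out
}

# light smoothing of an ordered pixel path (moving average, ends kept)
.smooth_path <- function(pts, k = 5) {
  n <- nrow(pts)
  if (n < k + 2) return(pts)
  sm <- apply(pts, 2, function(v) stats::filter(v, rep(1 / k, k), sides = 2))
  half <- (k - 1) / 2
  sm[seq_len(half), ] <- pts[seq_len(half), ]
  sm[(n - half + 1):n, ] <- pts[(n - half + 1):n, ]
  sm
}

# resample an ordered path at regular arc-length spacing (linear
# interpolation; endpoints kept) — removes pixel-level direction flicker
# before curvature-sign analysis
.resample_path <- function(pts, spacing = 4) {
  d <- sqrt(rowSums(diff(pts)^2))
  L <- sum(d)
  if (L <= spacing) return(pts[c(1, nrow(pts)), , drop = FALSE])
  s <- c(0, cumsum(d))
  grid <- unique(c(seq(0, L, by = spacing), L))
  cbind(stats::approx(s, pts[, 1], xout = grid, ties = "ordered")$y,
        stats::approx(s, pts[, 2], xout = grid, ties = "ordered")$y)
}

#' Tortuosity density of a vessel segment
#'
#' Grisan-type tortuosity density: the (lightly smoothed) centerline is
#' partitioned at curvature-sign inflection points into n subarcs of
#' constant curvature sign, and
#'   `tau = (n - 1)/n + (1/L) * sum_i (L_arc_i / L_chord_i - 1)`
#' where L is the total arc length of the segment. A straight segment has
#' one subarc with arc = chord, hence tau = 0; tau grows with both the
#' number of twists and how far each twist departs from its chord,
#' normalized per unit length.
#'
#' The centerline is lightly smoothed and resampled at regular arc-length
#' spacing (4 px) before analysis; curvature sign is the cross product of
#' successive tangent increments, and sign runs shorter than `min_run`
#' resampled points are treated as continuation (rasterization noise), not
#' inflections.
#'
#' @param segment a `vessel_segment`, or an ordered 2-column (row, col)
#'   coordinate matrix.
#' @param min_run minimum resampled points for a curvature-sign run to count.
#' @return dimensionless tortuosity density (>= 0).
#' @export
tortuosity_density <- function(segment, min_run = 2) {
  pts <- if (inherits(segment, "vessel_segment")) segment$points else segment
  if (nrow(pts) < 4) return(0)
  sm <- .resample_path(.smooth_path(pts))
  d <- diff(sm)
  step <- sqrt(rowSums(d^2))
  total_arc <- sum(step)
  if (total_arc <= 0) return(0)
  cross <- d[-nrow(d), 1] * d[-1, 2] - d[-nrow(d), 2] * d[-1, 1]
  sgn <- sign(cross) * (abs(cross) > 1e-9)
  # inflection = transition between curvature-sign runs of length >= min_run
  nz <- which(sgn != 0)
  bounds <- integer(0)
  if (length(nz)) {
    r <- rle(sgn[nz])
    keep <- r$lengths >= min_run
    if (sum(keep) > 1) {
      vals <- r$values[keep]
      run_starts <- (cumsum(r$lengths) - r$lengths + 1L)[keep]
      flip <- which(diff(vals) != 0) + 1L
      bounds <- nz[run_starts[flip]] + 1L  # vertex index in sm
    }
  }
  cuts <- sort(unique(c(1L, bounds, nrow(sm))))
  excess <- 0
  n_sub <- 0L
  for (i in seq_len(length(cuts) - 1)) {
    seg <- sm[cuts[i]:cuts[i + 1], , drop = FALSE]
    if (nrow(seg) < 2) next
    arc_i <- sum(sqrt(rowSums(diff(seg)^2)))
    chord_i <- sqrt(sum((seg[nrow(seg), ] - seg[1, ])^2))
    n_sub <- n_sub + 1L
    if (chord_i > 1e-9) excess <- excess + (arc_i / chord_i - 1)
  }
  n_sub <- max(1L, n_sub)
  (n_sub - 1) / n_sub + excess / total_arc
}

#' Region tortuosity density
#'
#' Segment-arc-length-weighted mean of [tortuosity_density()] over segments.
#'
#' @param segments list of `vessel_segment`s.
#' @param aggregation `"length_weighted"` or `"mean"`.
#' @return dimensionless value, `NA` if no segments.
#' @export
roi_tortuosity <- function(segments, aggregation = c("length_weighted", "mean")) {
  aggregation <- match.arg(aggregation)
  if (length(segments) == 0) return(NA_real_)
  tau <- vapply(segments, tortuosity_density, 0)
  len <- vapply(segments, `[[`, 0, "arc_length_px")
  if (aggregation == "length_weighted") sum(tau * len) / sum(len) else mean(tau)
}

#' Knudtson central retinal vessel equivalent
#'
#' Iterative Knudtson pairing of branch calibers: widths are sorted in
#' descending order and the current largest is repeatedly paired with the
#' current smallest, each pair being replaced by `k * sqrt(w1^2 + w2^2)`
#' with branching coefficient k = 0.88 for arteries (CRAE) and k = 0.95
#' for veins (CRVE), until a single value — the central vessel equivalent —
#' remains (an unpaired middle value carries over unchanged). The result is
#' permutation-invariant and positively homogeneous, so pixel and micron
#' computations commute with scaling.
#'
#' @param widths vessel widths (conventionally the mean widths of the six
#'   widest segments of the class in the region; see [crae_crve()]).
#' @param vessel_class `"artery"` or `"vein"`.
#' @return equivalent caliber in the units of `widths`.
#' @export
knudtson_equivalent <- function(widths, vessel_class = c("artery", "vein")) {
  vessel_class <- match.arg(vessel_class)
  if (any(!is.finite(widths) | widths <= 0))
    stop("widths must be positive and finite")
  if (length(widths) < 2) return(NA_real_)
  k <- if (vessel_class == "artery") 0.88 else 0.95  # Knudtson branching coefficients
  w <- sort(widths, decreasing = TRUE)
  while (length(w) > 1) {
    m <- length(w)
    npair <- m %/% 2
    paired <- k * sqrt(w[seq_len(npair)]^2 + w[m + 1 - seq_len(npair)]^2)
    mid <- if (m %% 2 == 1) w[npair + 1] else numeric(0)
    w <- sort(c(paired, mid), decreasing = TRUE)
  }
  w
}

#' CRAE/CRVE from region segments
#'
#' Selects the mean widths of the (up to) six widest segments of the class
#' within the region; with fewer than six available the largest even number
#' is used (with a warning); with fewer than two, `NA`.
#'
#' @param segments list of `vessel_segment`s for one vessel class.
#' @param vessel_class `"artery"` or `"vein"`.
#' @param n_widest number of branches the pairing starts from (default 6).
#' @return equivalent caliber in px, `NA` when undefined.
#' @export
crae_crve <- function(segments, vessel_class, n_widest = 6) {
  if (length(segments) < 2) return(NA_real_)
  wbar <- sort(vapply(segments, `[[`, 0, "mean_width_px"), decreasing = TRUE)
  wbar <- wbar[is.finite(wbar) & wbar > 0]
  if (length(wbar) < 2) return(NA_real_)
  if (length(wbar) < n_widest) {
    use <- 2 * (length(wbar) %/% 2)
    warning(sprintf("only %d segments available for %s equivalent; using %d",
                    length(wbar), vessel_class, use))
    wbar <- wbar[seq_len(use)]
  } else {
    wbar <- wbar[seq_len(n_widest)]
  }
  knudtson_equivalent(wbar, vessel_class)
}

#' Arteriole-to-venule ratio
#' @param crae,crve central retinal artery/vein equivalents (same units).
#' @return CRAE / CRVE, `NA` when either is undefined.
#' @export
avr <- function(crae, crve) {
  if (is.null(crae) || is.null(crve) || is.na(crae) || is.na(crve)) return(NA_real_)
  if (crve <= 0) stop("CRVE must be positive")
  crae / crve
}

# clip segments to an ROI: maximal runs of consecutive in-ROI points become
# (sub)segments; `midpoint` assigns whole segments by midpoint membership
.clip_segments <- function(segments, roi, min_segment_len = 10,
                           boundary_rule = c("clip", "midpoint")) {
  boundary_rule <- match.arg(boundary_rule)
  if (roi$name == "whole" && all(roi$mask == 1L)) return(segments)
  out <- list()
  for (seg in segments) {
    inside <- roi$mask[seg$points] == 1L
    if (boundary_rule == "midpoint") {
      mid <- seg$points[ceiling(nrow(seg$points) / 2), , drop = FALSE]
      if (roi$mask[mid] == 1L) out[[length(out) + 1L]] <- seg
      next
    }
    if (!any(inside)) next
    r <- rle(inside)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      pts <- seg$points[starts[i]:ends[i], , drop = FALSE]
      if (nrow(pts) < 3) next
      arc <- .path_arc_length(pts)
      if (arc < min_segment_len) next
      widths <- seg$widths_px[starts[i]:ends[i]]
      out[[length(out) + 1L]] <- structure(
        list(points = pts, widths_px = widths, arc_length_px = arc,
             chord_length_px = .path_chord_length(pts),
             mean_width_px = mean(widths)),
        class = "vessel_segment")
    }
  }
  out
}

#' Compute the full metric suite for a segmented image
#'
#' One record per (vessel class, region of interest) following the standard
#' metric-to-map assignment: vessel density, fractal dimension and global
#' caliber are whole-image-only metrics; local caliber and tortuosity
#' density are computed for every region; CRAE attaches to artery records,
#' CRVE to vein records, and AVR to the all-vessel record, in every region.
#' Macula-centered scans therefore produce 3 records (all/artery/vein x
#' whole image), disc-centered scans 9. Metrics undefined for a class or
#' region are `NA`, never 0. Micron columns are filled iff the image has a
#' known scale.
#'
#' @param bundle an `slo_bundle` (post-processed binary masks).
#' @param rois named list from [roi_set()].
#' @param image the analysed [slo_image()] (id, scale, metadata).
#' @param fovea,disc landmark results ([fovea_centroid()], [fit_disc()]).
#' @param config analysis parameters (see [default_config()]).
#' @return a tibble, one row per class x region.
#' @export
compute_all_metrics <- function(bundle, rois, image,
                                fovea = list(present = FALSE),
                                disc = list(present = FALSE),
                                config = default_config()) {
  min_len <- config$`metrics.min_segment_len` *
    sqrt(prod(bundle$native_resolution) / prod(WORKING_RESOLUTION))
  agg <- config$`metrics.aggregation`
  classes <- c(all = "vessel", artery = "artery", vein = "vein")
  segs <- lapply(classes, function(m) {
    if (!any(bundle$binary[[m]] > 0L)) list()
    else vessel_segments(bundle$binary[[m]], min_segment_len = min_len)
  })
  scale <- image$scale_um_per_px
  um <- function(v) if (is.na(scale)) NA_real_ else v * scale

  rows <- list()
  for (roi_name in names(rois)) {
    roi <- rois[[roi_name]]
    clipped <- lapply(segs, .clip_segments, roi = roi, min_segment_len = min_len,
                      boundary_rule = config$`zones.boundary_rule`)
    cr <- if (length(clipped$artery))
      crae_crve(clipped$artery, "artery", config$`metrics.knudtson_n`) else NA_real_
    cv <- if (length(clipped$vein))
      crae_crve(clipped$vein, "vein", config$`metrics.knudtson_n`) else NA_real_
    for (cls in names(classes)) {
      m <- bundle$binary[[classes[[cls]]]]
      nonempty <- any(m > 0L)
      whole_only <- roi$name == "whole"
      dens <- fd <- gc_px <- NA_real_
      if (whole_only && nonempty) {
        dens <- vessel_density(m, roi)
        fd <- suppressWarnings(
          fractal_dimension(m, roi, on_skeleton = config$`metrics.fd_on_skeleton`))
        gc_px <- global_caliber(m)
      } else if (whole_only && !nonempty) {
        dens <- 0
      }
      lc_px <- local_caliber(clipped[[cls]], aggregation = agg)
      tau <- roi_tortuosity(clipped[[cls]], aggregation = agg)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        image_id = image$image_id, vessel_class = cls, roi = roi$name,
        laterality = image$laterality, location = image$location,
        scale_um_per_px = scale,
        fovea_x_px = if (isTRUE(fovea$present)) fovea$x_px else NA_real_,
        fovea_y_px = if (isTRUE(fovea$present)) fovea$y_px else NA_real_,
        disc_x_px = if (isTRUE(disc$present)) disc$x_px else NA_real_,
        disc_y_px = if (isTRUE(disc$present)) disc$y_px else NA_real_,
        disc_diameter_px = if (isTRUE(disc$present)) disc$diameter_px else NA_real_,
        n_segments = length(clipped[[cls]]),
        vessel_density = dens, fractal_dimension = fd,
        global_caliber_px = gc_px, global_caliber_um = um(gc_px),
        local_caliber_px = lc_px, local_caliber_um = um(lc_px),
        tortuosity_density = tau,
        crae_px = if (cls == "artery") cr else NA_real_,
        crae_um = if (cls == "artery") um(cr) else NA_real_,
        crve_px = if (cls == "vein") cv else NA_real_,
        crve_um = if (cls == "vein") um(cv) else NA_real_,
        avr = if (cls == "all") avr(cr, cv) else NA_real_)
    }
  }
  dplyr::bind_rows(rows)
}
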
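# Binary-mask post-processing and landmark geometry: thresholding, small
# false-positive removal, gap bridging, fovea centroid, optic-disc ellipse
# fit, and laterality/location inference.

#' Threshold a probability map
#'
#' Pixels with `p >= threshold` are included (the boundary value itself is
#' retained — an all-0.5 map thresholds to all ones).
#'
#' @param prob numeric matrix with values in [0, 1].
#' @param threshold inclusion threshold (default 0.5).
#' @return binary integer matrix.
#' @export
binarize <- function(prob, threshold = 0.5) {
  stopifnot(is.matrix(prob))
  if (any(prob < -1e-9 | prob > 1 + 1e-9, na.rm = TRUE))
    stop("probability map has values outside [0, 1]")
  (prob >= threshold) * 1L
}

#' Remove small connected components
#'
#' Deletes 8-connected components with area strictly below `min_area_px`
#' (a component of exactly `min_area_px` pixels is retained). Used to remove
#' small false-positive regions after thresholding.
#'
#' @param mask binary matrix.
#' @param min_area_px minimum retained component area in pixels.
#' @return binary integer matrix.
#' @export
clean_mask <- function(mask, min_area_px = 10) {
  stopifnot(min_area_px >= 0)
  b <- .as_binary(mask)
  if (!any(b > 0L) || min_area_px <= 1) return(b)
  lab <- label_components8(b)
  areas <- tabulate(lab[lab > 0L])
  drop <- which(areas < min_area_px)
  if (length(drop)) b[lab %in% drop] <- 0L
  b
}

# local tangent (unit vector, pointing outward through the endpoint) from
# the last up-to-5 ordered skeleton points of a path ending at `end`
.endpoint_tangent <- function(pts, endpoint_row) {
  n <- nrow(pts)
  if (all(pts[1, ] == endpoint_row)) pts <- pts[n:1, , drop = FALSE]
  k <- min(5L, n - 1L)
  v <- pts[n, ] - pts[n - k, ]
  len <- sqrt(sum(v^2))
  if (len < 1e-9) c(0, 0) else v / len
}

#' Bridge small gaps between vessel components
#'
#' Skeleton endpoints of different 8-connected components are joined when
#' (a) the empty gap between the two components (minimum inter-component
#' pixel-center distance minus 1) is at most `max_gap_px`, and (b) the local
#' tangents at the two endpoints are roughly collinear: each deviates by at
#' most `max_angle_deg` from the line joining the endpoints. The join is
#' drawn as a stroke of the local vessel width, so the number of connected
#' components never increases.
#'
#' @param mask binary matrix.
#' @param max_gap_px maximum bridged gap in pixels (default 3).
#' @param max_angle_deg collinearity tolerance (default 30 degrees).
#' @return binary integer matrix.
#' @export
bridge_gaps <- function(mask, max_gap_px = 3, max_angle_deg = 30) {
  stopifnot(max_gap_px >= 0)
  b <- .as_binary(mask)
  if (!any(b > 0L) || max_gap_px == 0) return(b)
  lab <- label_components8(b)
  if (max(lab) < 2L) return(b)
  skel <- skeletonize(b)
  deg <- count_neighbors8(skel)
  ends <- which(skel == 1L & deg <= 1L, arr.ind = TRUE)
  if (nrow(ends) < 2) return(b)
  dtm <- .dist_transform(b)
  end_comp <- lab[ends]
  # candidate endpoint pairs from different components, close enough that a
  # gap <= max_gap is geometrically possible given skeleton retraction
  paths <- .skeleton_paths(skel)
  tangents <- matrix(0, nrow(ends), 2)
  for (i in seq_len(nrow(ends))) {
    owner <- NULL
    for (p in paths) {
      if (any(p[, 1] == ends[i, 1] & p[, 2] == ends[i, 2])) { owner <- p; break }
    }
    if (!is.null(owner) && nrow(owner) >= 2)
      tangents[i, ] <- .endpoint_tangent(owner, ends[i, ])
  }
  widths <- 2 * dtm[ends] - 1
  cosmax <- cos(max_angle_deg * pi / 180)
  added <- b
  for (i in seq_len(nrow(ends) - 1)) {
    for (j in (i + 1):nrow(ends)) {
      if (end_comp[i] == end_comp[j]) next
      d <- sqrt(sum((ends[j, ] - ends[i, ])^2))
      if (d > max_gap_px + widths[i] / 2 + widths[j] / 2 + 2) next
      # true inter-mask gap near the two endpoints
      gap <- .local_component_gap(b, lab, end_comp[i], end_comp[j],
                                  ends[i, ], ends[j, ],
                                  radius = ceiling(d) + 3L)
      if (is.na(gap) || gap > max_gap_px) next
      u <- ends[j, ] - ends[i, ]
      u <- u / max(sqrt(sum(u^2)), 1e-9)
      if (sum(tangents[i, ]^2) > 0 && sum(u * tangents[i, ]) < cosmax) next
      if (sum(tangents[j, ]^2) > 0 && sum(-u * tangents[j, ]) < cosmax) next
      w <- max(1, mean(widths[c(i, j)]))
      stroke <- .stroke_mask(rbind(ends[i, ] - 1, ends[j, ] - 1), w,
                             nrow(b), ncol(b))
      added <- .as_binary(added | stroke)
    }
  }
  added
}

# minimum pixel-center distance between two labelled components inside a
# window around the two endpoints, minus 1 (adjacent pixels -> gap 0)
.local_component_gap <- function(mask, lab, c1, c2, e1, e2, radius) {
  r_lo <- max(1L, min(e1[1], e2[1]) - radius)
  r_hi <- min(nrow(mask), max(e1[1], e2[1]) + radius)
  c_lo <- max(1L, min(e1[2], e2[2]) - radius)
  c_hi <- min(ncol(mask), max(e1[2], e2[2]) + radius)
  w <- lab[r_lo:r_hi, c_lo:c_hi]
  p1 <- which(w == c1, arr.ind = TRUE)
  p2 <- which(w == c2, arr.ind = TRUE)
  if (!nrow(p1) || !nrow(p2)) return(NA_real_)
  d2 <- outer(p1[, 1], p2[, 1], `-`)^2 + outer(p1[, 2], p2[, 2], `-`)^2
  sqrt(min(d2)) - 1
}

#' Fovea pit from a fovea mask
#'
#' The foveal pit is the centroid (arithmetic mean of member pixel
#' coordinates) of the fovea binary mask. Coordinates are 0-based,
#' `x = column`, `y = row`.
#'
#' @param mask binary fovea mask.
#' @return list with `x_px`, `y_px`, `present`.
#' @export
fovea_centroid <- function(mask) {
  b <- .as_binary(mask)
  if (!any(b > 0L))
    return(list(x_px = NA_real_, y_px = NA_real_, present = FALSE))
  px <- which(b == 1L, arr.ind = TRUE)
  list(x_px = mean(px[, 2]) - 1, y_px = mean(px[, 1]) - 1, present = TRUE)
}

#' Fit the optic disc as an ellipse
#'
#' The largest 8-connected component of the disc mask is modelled as an
#' ellipse by image moments: the center is the centroid and the axis
#' lengths come from the second central moments (a uniform ellipse with
#' semi-axis a has variance a^2/4 along that axis). The disc diameter D is
#' the mean of the major and minor axis lengths.
#'
#' @param mask binary optic-disc mask.
#' @return list with `x_px`, `y_px` (0-based center), `diameter_px`,
#'   `major_px`, `minor_px`, `present`.
#' @export
fit_disc <- function(mask) {
  b <- .as_binary(mask)
  if (!any(b > 0L))
    return(list(x_px = NA_real_, y_px = NA_real_, diameter_px = NA_real_,
                major_px = NA_real_, minor_px = NA_real_, present = FALSE))
  lab <- label_components8(b)
  areas <- tabulate(lab[lab > 0L])
  keep <- which.max(areas)
  px <- which(lab == keep, arr.ind = TRUE)
  y <- px[, 1] - 1; x <- px[, 2] - 1
  cy <- mean(y); cx <- mean(x)
  covm <- stats::cov(cbind(y, x)) * (length(y) - 1) / length(y)
  ev <- eigen(covm, symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  axes <- 4 * sqrt(ev)  # full axis lengths, descending
  list(x_px = cx, y_px = cy,
       diameter_px = mean(axes), major_px = axes[1], minor_px = axes[2],
       present = TRUE)
}

#' Infer laterality and location from detected landmarks
#'
#' Rules (in order):
#' * location: `"disc"` if the disc center lies within the central third of
#'   the image width; else `"macula"` if the fovea lies within the central
#'   third; else `"unknown"`.
#' * laterality: if both landmarks are present, the disc right of the fovea
#'   means a right eye and vice versa; if only the disc is present in a
#'   disc-centered image, disc in the right half means right eye; ties and
#'   undecidable cases return `"unknown"` rather than guessing.
#'
#' @param fovea result of [fovea_centroid()].
#' @param disc result of [fit_disc()].
#' @param image_shape `c(height, width)` in pixels.
#' @return list with `laterality` and `location`.
#' @export
infer_laterality_location <- function(fovea, disc, image_shape) {
  w <- image_shape[2]
  third <- c(w / 3, 2 * w / 3)
  location <- "unknown"
  if (isTRUE(disc$present) && disc$x_px >= third[1] && disc$x_px <= third[2]) {
    location <- "disc"
  } else if (isTRUE(fovea$present) && fovea$x_px >= third[1] && fovea$x_px <= third[2]) {
    location <- "macula"
  }
  laterality <- "unknown"
  if (isTRUE(fovea$present) && isTRUE(disc$present)) {
    if (disc$x_px > fovea$x_px) laterality <- "right"
    else if (disc$x_px < fovea$x_px) laterality <- "left"
  } else if (isTRUE(disc$present) && location == "disc") {
    if (disc$x_px > w / 2) laterality <- "right"
    else if (disc$x_px < w / 2) laterality <- "left"
  }
  if (!isTRUE(fovea$present) && !isTRUE(disc$present))
    warning("no landmarks detected; laterality/location unknown")
  list(laterality = laterality, location = location)
}
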
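# Regions of interest: the whole image for every scan, plus the standard
# peripapillary annuli for disc-centered scans — zone B from half a disc
# diameter beyond the disc margin to a full diameter (radii [1.0 D, 1.5 D]
# from the disc center for a disc of diameter D), and zone C from the margin
# to two diameters away (radii [0.5 D, 2.5 D]).

.new_roi <- function(name, mask) {
  structure(list(name = name, mask = .as_binary(mask),
                 area_px = sum(mask > 0)), class = "roi_mask")
}

#' Whole-image region of interest
#' @param image_shape `c(height, width)`.
#' @return an `roi_mask` covering every pixel.
#' @export
whole_image_roi <- function(image_shape) {
  .new_roi("whole", matrix(1L, image_shape[1], image_shape[2]))
}

#' Peripapillary zone B or C
#'
#' The fitted disc is circularized to radius D/2 at the ellipse center
#' (`shape = "circular"`, the default); zone B keeps pixels whose distance r
#' from the center satisfies `D <= r <= 1.5 D`, zone C `0.5 D <= r <= 2.5 D`,
#' clipped to the image bounds. `shape = "elliptical"` offsets from the
#' fitted ellipse margin instead (normalized elliptical radius).
#'
#' @param disc a [fit_disc()] result (must be present with D > 0).
#' @param which `"B"` or `"C"`.
#' @param image_shape `c(height, width)`.
#' @param shape `"circular"` or `"elliptical"`.
#' @return an `roi_mask`.
#' @export
zone_roi <- function(disc, which = c("B", "C"), image_shape,
                     shape = c("circular", "elliptical")) {
  which <- match.arg(which)
  shape <- match.arg(shape)
  if (!isTRUE(disc$present) || !is.finite(disc$diameter_px) || disc$diameter_px <= 0)
    stop("zones are undefined without a detected optic disc")
  D <- disc$diameter_px
  band <- if (which == "B") c(1.0, 1.5) * D else c(0.5, 2.5) * D
  if (shape == "circular") {
    r <- .radius_field(image_shape[1], image_shape[2], disc$y_px, disc$x_px)
  } else {
    ry <- ((seq_len(image_shape[1]) - 1) - disc$y_px)^2 / (disc$minor_px / 2)^2
    cx <- ((seq_len(image_shape[2]) - 1) - disc$x_px)^2 / (disc$major_px / 2)^2
    r <- (sqrt(outer(ry, cx, `+`)) - 1) * D / 2 + D / 2  # margin-relative
  }
  .new_roi(paste0("zone", which), (r >= band[1] & r <= band[2]) * 1L)
}

#' Restrict a mask to a region of interest
#'
#' Elementwise AND: pixels outside the ROI never contribute to that ROI's
#' metrics.
#'
#' @param mask binary matrix.
#' @param roi an `roi_mask`.
#' @return binary integer matrix.
#' @export
restrict <- function(mask, roi) {
  stopifnot(all(dim(mask) == dim(roi$mask)))
  .as_binary(mask * roi$mask)
}

#' Region-of-interest set for a scan location
#'
#' Macula-centered (and unknown-location) scans get the whole image only;
#' disc-centered scans additionally get zones B and C.
#'
#' @param location `"macula"`, `"disc"` or `"unknown"`.
#' @param disc [fit_disc()] result (needed for zones).
#' @param image_shape `c(height, width)`.
#' @param shape zone geometry, see [zone_roi()].
#' @param exclude_disc_from_whole remove the disc-ellipse interior from the
#'   whole-image ROI.
#' @return named list of `roi_mask` objects.
#' @export
roi_set <- function(location, disc, image_shape,
                    shape = "circular", exclude_disc_from_whole = FALSE) {
  whole <- whole_image_roi(image_shape)
  if (isTRUE(exclude_disc_from_whole) && isTRUE(disc$present)) {
    inside <- .radius_field(image_shape[1], image_shape[2],
                            disc$y_px, disc$x_px) < disc$diameter_px / 2
    whole <- .new_roi("whole", whole$mask * (1L - inside))
  }
  out <- list(whole = whole)
  if (identical(location, "disc")) {
    out$zoneB <- zone_roi(disc, "B", image_shape, shape)
    out$zoneC <- zone_roi(disc, "C", image_shape, shape)
  }
  out
}
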
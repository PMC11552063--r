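# Shared fixtures: small deterministic masks and scenes built in code.

# axis-aligned straight vessel with exactly rasterized caliber: odd widths
# sit on a pixel-center row/column, even widths on a half-pixel offset, and
# ends are butt-capped, so the drawn cross-section is exactly `width` pixels
straight_vessel_mask <- function(width, length = 400, orientation = c("h", "v"),
                                 canvas = NULL) {
  orientation <- match.arg(orientation)
  margin <- 12
  h <- 2 * margin + width + 6
  if (is.null(canvas)) canvas <- if (orientation == "h")
    c(ceiling(h), length + 2 * margin) else c(length + 2 * margin, ceiling(h))
  c0 <- if (width %% 2 == 1) margin + ceiling(width / 2) else
    margin + width / 2 + 0.5
  if (orientation == "h") {
    pts <- rbind(c(c0, margin), c(c0, margin + length - 1))
  } else {
    pts <- rbind(c(margin, c0), c(margin + length - 1, c0))
  }
  render_vessel(synth_polyline(pts, max(width, 1)), canvas,
                width_px = width, butt = TRUE)
}

# filled circle mask of given radius at a (0-based) center
circle_mask <- function(nr, nc, y0, x0, radius) {
  (slomorph:::.radius_field(nr, nc, y0, x0) <= radius) * 1L
}

# a quick macula-centered scene at full working size
demo_scene <- function(seed = 3, location = "macula", noise_sd = 0.01, ...) {
  generate_scene(random_scene_spec(location, seed = seed,
                                   noise_sd = noise_sd, ...))
}

# random blob/stroke mask for property-style loops
random_stroke_mask <- function(seed, nr = 120, nc = 120) {
  slomorph:::.with_seed(seed, {
    m <- matrix(0L, nr, nc)
    for (i in seq_len(3)) {
      p0 <- runif(2, 15, nr - 15)
      ang <- runif(1, 0, 2 * pi)
      len <- runif(1, 20, 60)
      p1 <- pmin(pmax(p0 + len * c(sin(ang), cos(ang)), 5), nr - 5)
      m <- m | render_vessel(synth_polyline(rbind(p0, p1), runif(1, 2, 6)),
                             c(nr, nc))
    }
    slomorph:::.as_binary(m)
  })
}

# segmentation bundle straight from a scene's ground truth (no files)
truth_bundle <- function(scene) {
  tr <- scene$truth
  shape <- dim(tr$vessel)
  zero <- matrix(0L, shape[1], shape[2])
  binary <- list(vessel = tr$vessel,
                 artery = tr$artery, vein = tr$vein,
                 disc = if (is.null(tr$disc_mask)) zero else tr$disc_mask,
                 fovea = tr$fovea_mask)
  slomorph:::.new_bundle(lapply(binary, function(b) b * 1), binary,
                         shape, "external")
}

# full metric records for a scene using its ground-truth segmentation
analyze_scene_records <- function(scene, config = default_config()) {
  b <- truth_bundle(scene)
  fovea <- fovea_centroid(b$binary$fovea)
  disc <- fit_disc(b$binary$disc)
  rois <- roi_set(scene$image$location, disc, dim(scene$image$pixels))
  compute_all_metrics(b, rois, scene$image, fovea, disc, config)
}

expect_matrix_equal <- function(a, b) {
  expect_identical(dim(a), dim(b))
  expect_true(all(a == b))
}
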
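# Synthetic SLO scene generator: dark-background grayscale images with
# bright ridge-profiled vessel trees branching from an elliptical disc-like
# region, a dark foveal spot, optional central light reflex, seeded noise --
# with exact ground-truth masks and analytically known widths, arc lengths
# and tortuosities. Every downstream stage is testable against these scenes
# without any external data.

# run expr with a temporarily seeded RNG, restoring global state afterwards
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Define a vessel centerline
#'
#' Two parametric centerline families are supported. `synth_polyline()` takes
#' explicit control points (continuous 0-based `(y, x)` coordinates); its
#' analytic arc length is the summed segment length. `synth_sinusoid()` is a
#' horizontal baseline at row `y0` from `x0` over `length_px` columns with
#' transverse displacement `amplitude * sin(2*pi*(x - x0)/period)`; its arc
#' length is evaluated by adaptive quadrature of the exact integrand.
#'
#' @param points numeric matrix with columns `(y, x)`.
#' @param width_px constant vessel width in pixels (>= 1).
#' @param class `"artery"` or `"vein"`.
#' @return a `synth_curve` list with fields `xy` (dense samples, step <= 0.5
#'   px), `width_px`, `class`, `arc_length_px`, `chord_length_px`.
#' @export
synth_polyline <- function(points, width_px, class = c("vein", "artery")) {
  class <- match.arg(class)
  stopifnot(is.matrix(points), ncol(points) == 2, nrow(points) >= 2)
  if (width_px < 1) stop("vessel width must be >= 1 px")
  seglen <- sqrt(rowSums((points[-1, , drop = FALSE] -
                          points[-nrow(points), , drop = FALSE])^2))
  xy <- do.call(rbind, lapply(seq_len(nrow(points) - 1), function(i) {
    n <- max(2L, ceiling(seglen[i] / 0.4) + 1L)
    tt <- seq(0, 1, length.out = n)
    cbind(points[i, 1] + tt * (points[i + 1, 1] - points[i, 1]),
          points[i, 2] + tt * (points[i + 1, 2] - points[i, 2]))
  }))
  structure(list(kind = "polyline", xy = xy, width_px = width_px,
                 class = class,
                 arc_length_px = sum(seglen),
                 chord_length_px = sqrt(sum((points[nrow(points), ] - points[1, ])^2))),
            class = "synth_curve")
}

#' @rdname synth_polyline
#' @param y0,x0 start of the baseline (continuous, 0-based).
#' @param length_px extent along the baseline.
#' @param amplitude,period sinusoid amplitude and period in pixels.
#' @export
synth_sinusoid <- function(y0, x0, length_px, amplitude, period, width_px,
                           class = c("vein", "artery")) {
  class <- match.arg(class)
  if (width_px < 1) stop("vessel width must be >= 1 px")
  omega <- 2 * pi / period
  n <- max(3L, ceiling(length_px * sqrt(1 + (amplitude * omega)^2) / 0.4) + 1L)
  tt <- seq(0, length_px, length.out = n)
  xy <- cbind(y0 + amplitude * sin(omega * tt), x0 + tt)
  arc <- stats::integrate(function(t) sqrt(1 + (amplitude * omega)^2 * cos(omega * t)^2),
                          0, length_px, rel.tol = 1e-10,
                          subdivisions = 1000L)$value
  structure(list(kind = "sinusoid", xy = xy, width_px = width_px,
                 class = class, amplitude = amplitude, period = period,
                 arc_length_px = arc,
                 chord_length_px = sqrt(sum((xy[n, ] - xy[1, ])^2))),
            class = "synth_curve")
}

#' Rasterize a vessel centerline
#'
#' Disc-brush stroke: the mask is the set of pixels whose (0-based) center
#' lies within `width/2` of the densely sampled centerline, so the drawn
#' vessel has known constant caliber. `butt = TRUE` omits the rounded end
#' caps (calibration fixtures with exactly rectangular cross-section).
#'
#' @param curve a `synth_curve` (or a dense 2-column `(y, x)` matrix).
#' @param width_px stroke width; defaults to the curve's own width.
#' @param canvas `c(height, width)` of the target canvas in pixels.
#' @param butt drop end caps.
#' @return binary integer matrix.
#' @export
render_vessel <- function(curve, canvas, width_px = NULL, butt = FALSE) {
  xy <- if (inherits(curve, "synth_curve")) curve$xy else curve
  if (is.null(width_px))
    width_px <- if (inherits(curve, "synth_curve")) curve$width_px else
      stop("width_px required for bare coordinate input")
  .stroke_mask(xy, width_px, canvas[1], canvas[2], butt = butt)
}

#' Specify a synthetic SLO scene
#'
#' Defaults emulate a 768 x 768, 30-degree-field macula- or disc-centered
#' infrared SLO localizer at roughly 11.71 microns per pixel: an optic disc
#' of ~1.5 mm (128 px) diameter, a dark foveal spot, and vessels of 6-13 px
#' caliber with arteries rendered slightly thinner and dimmer than veins.
#'
#' @param size_px image side length (square canvas).
#' @param curves list of `synth_curve` objects.
#' @param disc_center `(y, x)` 0-based center of the disc ellipse, or `NULL`
#'   for no disc in the field of view.
#' @param disc_diameter_px mean disc diameter D; the rendered ellipse has
#'   axes `(1.1, 0.9) * D` so the fitted D equals `disc_diameter_px`.
#' @param fovea_center `(y, x)` of the foveal pit, or `NULL`.
#' @param background,vessel_contrast base intensity and added ridge contrast
#'   (veins; arteries get `artery_contrast_factor` of it) in [0, 1] units.
#' @param artery_contrast_factor relative artery brightness (< 1).
#' @param reflex add a central light-reflex strip of width `width/3` along
#'   each centerline.
#' @param fovea_depth,fovea_sigma_px depth and Gaussian radius of the dark
#'   foveal spot.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param scale_um_per_px spatial scale stored with the image.
#' @param laterality,location metadata recorded in the generated image.
#' @param seed integer; fully determines the rendered scene.
#' @param image_id identifier.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(size_px = 768, curves = list(),
                           disc_center = NULL, disc_diameter_px = 128,
                           fovea_center = NULL,
                           background = 0.25, vessel_contrast = 0.35,
                           artery_contrast_factor = 0.8,
                           reflex = FALSE,
                           fovea_depth = 0.12, fovea_sigma_px = 30,
                           noise_sd = 0.02,
                           scale_um_per_px = 9000 / 768,
                           laterality = "unknown", location = "unknown",
                           seed = 1L, image_id = "synthetic") {
  if (!is.null(disc_center) && !is.null(fovea_center)) {
    if (sqrt(sum((disc_center - fovea_center)^2)) < disc_diameter_px / 2 + fovea_sigma_px)
      stop("disc and fovea overlap; move the landmarks apart")
  }
  for (cv in curves) {
    rng <- apply(cv$xy, 2, range)
    if (rng[1, 1] < 0 || rng[1, 2] < 0 ||
        rng[2, 1] > size_px - 1 || rng[2, 2] > size_px - 1)
      stop("curve extends outside the ", size_px, "x", size_px, " canvas")
  }
  structure(list(size_px = size_px, curves = curves,
                 disc_center = disc_center, disc_diameter_px = disc_diameter_px,
                 fovea_center = fovea_center,
                 background = background, vessel_contrast = vessel_contrast,
                 artery_contrast_factor = artery_contrast_factor,
                 reflex = reflex, fovea_depth = fovea_depth,
                 fovea_sigma_px = fovea_sigma_px, noise_sd = noise_sd,
                 scale_um_per_px = scale_um_per_px,
                 laterality = laterality, location = location,
                 seed = as.integer(seed), image_id = image_id),
            class = "synthetic_spec")
}

# distance-to-centerline field for ridge shading, Inf off the vessel
# support; windowed per polyline segment so long curves stay cheap
.stroke_distance <- function(xy, width, nr, nc) {
  half <- width / 2
  d2full <- matrix(Inf, nr, nc)
  pad <- half + 2.5
  xy <- .sparsify_polyline(xy)
  n <- nrow(xy)
  for (i in seq_len(max(1L, n - 1L))) {
    p <- xy[i, ]; q <- xy[min(i + 1L, n), ]
    r_lo <- max(1L, floor(min(p[1], q[1]) - pad) + 1L)
    r_hi <- min(nr, ceiling(max(p[1], q[1]) + pad) + 1L)
    c_lo <- max(1L, floor(min(p[2], q[2]) - pad) + 1L)
    c_hi <- min(nc, ceiling(max(p[2], q[2]) + pad) + 1L)
    if (r_lo > r_hi || c_lo > c_hi) next
    gr <- matrix((r_lo:r_hi) - 1, r_hi - r_lo + 1L, c_hi - c_lo + 1L)
    gc <- matrix((c_lo:c_hi) - 1, r_hi - r_lo + 1L, c_hi - c_lo + 1L,
                 byrow = TRUE)
    v <- q - p
    len2 <- sum(v^2)
    wr <- gr - p[1]; wc <- gc - p[2]
    d2 <- if (len2 < 1e-12) {
      wr^2 + wc^2
    } else {
      tcl <- pmin(pmax((wr * v[1] + wc * v[2]) / len2, 0), 1)
      (wr - tcl * v[1])^2 + (wc - tcl * v[2])^2
    }
    d2full[r_lo:r_hi, c_lo:c_hi] <- pmin(d2full[r_lo:r_hi, c_lo:c_hi], d2)
  }
  sqrt(d2full)
}

#' Render a synthetic scene
#'
#' Composes background + raised-cosine vessel ridges (+ optional central
#' light reflex) + dark Gaussian foveal spot + bright elliptical disc +
#' seeded Gaussian noise, and returns both the image and its exact ground
#' truth.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `image` (an [slo_image()]) and `truth` (list: `labels`
#'   mask with the 0/1/2/3/4 encoding, `vessel` binary mask, `fovea_mask`,
#'   `fovea` 0-based `(x, y)` or `NULL`, `disc` list(center, axes, diameter)
#'   or `NULL`, `curves` tibble of per-curve analytic arc/chord/width).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$size_px
  img <- matrix(spec$background, n, n)
  labels <- matrix(0L, n, n)
  artery <- matrix(0L, n, n)
  vein <- matrix(0L, n, n)

  disc <- NULL
  if (!is.null(spec$disc_center)) {
    D <- spec$disc_diameter_px
    semi_major <- 1.1 * D / 2
    semi_minor <- 0.9 * D / 2
    dm <- .ellipse_mask(n, n, spec$disc_center[1], spec$disc_center[2],
                        semi_minor, semi_major)  # major axis horizontal
    img[dm == 1L] <- spec$background + 0.30
    disc <- list(center = spec$disc_center, diameter_px = D,
                 axes_px = c(major = 2 * semi_major, minor = 2 * semi_minor),
                 mask = dm)
  }

  for (cv in spec$curves) {
    d <- .stroke_distance(cv$xy, cv$width_px, n, n)
    half <- cv$width_px / 2
    inside <- d <= half + 1e-9
    contrast <- spec$vessel_contrast *
      if (cv$class == "artery") spec$artery_contrast_factor else 1
    prof <- matrix(0, n, n)
    prof[inside] <- contrast * 0.5 * (1 + cos(pi * d[inside] / half))
    if (isTRUE(spec$reflex))
      prof[d <= half / 3] <- prof[d <= half / 3] + 0.5 * contrast
    img <- pmax(img, spec$background + prof)
    if (cv$class == "artery") artery[inside] <- 1L else vein[inside] <- 1L
  }
  vessel <- .as_binary(artery | vein)
  labels[artery == 1L] <- 1L
  labels[vein == 1L] <- 2L
  labels[artery == 1L & vein == 1L] <- 3L
  if (!is.null(disc)) labels[disc$mask == 1L & vessel == 0L] <- 4L

  fovea_mask <- matrix(0L, n, n)
  if (!is.null(spec$fovea_center)) {
    r <- .radius_field(n, n, spec$fovea_center[1], spec$fovea_center[2])
    img <- img - spec$fovea_depth * exp(-(r^2) / (2 * spec$fovea_sigma_px^2))
    fovea_mask[r <= 60] <- 1L  # 60 px fovea label radius convention
  }

  if (spec$noise_sd > 0)
    img <- img + .with_seed(spec$seed,
                            matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n))
  img <- pmin(pmax(img, 0), 1)

  curves_tbl <- tibble::tibble(
    curve_id = seq_along(spec$curves),
    class = vapply(spec$curves, `[[`, "", "class"),
    width_px = vapply(spec$curves, `[[`, 0, "width_px"),
    arc_length_px = vapply(spec$curves, `[[`, 0, "arc_length_px"),
    chord_length_px = vapply(spec$curves, `[[`, 0, "chord_length_px"))

  image <- slo_image(img, scale_um_per_px = spec$scale_um_per_px,
                     laterality = spec$laterality, location = spec$location,
                     image_id = spec$image_id)
  truth <- list(
    labels = labels, vessel = vessel,
    artery = artery, vein = vein,
    fovea_mask = fovea_mask,
    fovea = if (is.null(spec$fovea_center)) NULL else
      c(x = spec$fovea_center[2], y = spec$fovea_center[1]),
    disc = if (is.null(disc)) NULL else disc[c("center", "diameter_px", "axes_px")],
    disc_mask = if (is.null(disc)) NULL else disc$mask,
    curves = curves_tbl)
  list(image = image, truth = truth)
}

#' Random plausible scene specification
#'
#' Draws a vessel tree of smooth polylines radiating from the optic disc
#' (superior and inferior arcades plus straighter nasal vessels), paired
#' artery/vein trajectories so arteriovenous crossings occur, for either a
#' macula-centered scene (fovea central, disc at the nasal edge) or a
#' disc-centered scene (disc central).
#'
#' @param location `"macula"` or `"disc"`.
#' @param seed integer seed; fully determines the spec.
#' @param size_px canvas side.
#' @param n_vessel_pairs number of artery/vein pairs.
#' @param laterality `"right"` or `"left"` (mirrors the geometry).
#' @param ... passed through to [synthetic_spec()].
#' @return a [synthetic_spec()].
#' @export
random_scene_spec <- function(location = c("macula", "disc"), seed = 1L,
                              size_px = 768, n_vessel_pairs = 4,
                              laterality = "right", ...) {
  location <- match.arg(location)
  .with_seed(seed, {
    n <- size_px
    sgn <- if (laterality == "right") 1 else -1  # disc on the right for OD
    if (location == "disc") {
      disc_center <- c(n / 2, n / 2)
      fovea_center <- NULL
    } else {
      disc_center <- c(n / 2, if (sgn > 0) n - 60 else 60)
      fovea_center <- c(n / 2, n / 2)
    }
    D <- 128
    curves <- list()
    for (i in seq_len(n_vessel_pairs)) {
      # arcades leave the disc up/down and curve toward the temporal side
      up <- if (i %% 2 == 0) -1 else 1
      theta0 <- up * stats::runif(1, 55, 80) * pi / 180
      for (cls in c("vein", "artery")) {
        w <- if (cls == "vein") stats::runif(1, 9, 13) else stats::runif(1, 6, 9)
        heading <- theta0 + stats::runif(1, -0.08, 0.08)
        pos <- disc_center + 0.45 * D * c(sin(heading), -sgn * cos(heading))
        pts <- matrix(pos, 1, 2)
        step <- 22
        bend <- -up * stats::runif(1, 0.020, 0.040)  # sweep temporally
        for (s in seq_len(34)) {
          heading <- heading + bend + stats::rnorm(1, 0, 0.01)
          pos <- pos + step * c(sin(heading), -sgn * cos(heading))
          if (any(pos < 18) || any(pos > n - 19)) break
          pts <- rbind(pts, pos)
        }
        if (nrow(pts) >= 4)
          curves <- c(curves, list(synth_polyline(pts, w, cls)))
      }
    }
    synthetic_spec(size_px = n, curves = curves, disc_center = disc_center,
                   disc_diameter_px = D, fovea_center = fovea_center,
                   laterality = laterality, location = location,
                   seed = seed, image_id = sprintf("scene_%s_%d", location, seed),
                   ...)
  })
}

#' Generate an unregistered repeated pair of scenes
#'
#' Two renderings of the same vessel tree differing only by a small
#' translation and independent noise realizations, emulating repeated SLO
#' capture of one eye without registration. Ground truths are translated
#' consistently.
#'
#' @param spec a [synthetic_spec()].
#' @param jitter `(dy, dx)` integer translation applied to the second scene
#'   (each component <= 10 px in magnitude).
#' @param noise_seeds two integers for the two noise realizations.
#' @return list of two `generate_scene()` results.
#' @export
generate_repeated_pair <- function(spec, jitter = c(0, 0),
                                   noise_seeds = spec$seed + c(0L, 1L)) {
  if (any(abs(jitter) > 10)) stop("jitter must be a small translation (<= 10 px)")
  spec1 <- spec
  spec1$seed <- as.integer(noise_seeds[1])
  spec2 <- .translate_spec(spec, jitter)
  spec2$seed <- as.integer(noise_seeds[2])
  spec2$image_id <- paste0(spec$image_id, "_repeat")
  list(generate_scene(spec1), generate_scene(spec2))
}

.translate_spec <- function(spec, jitter) {
  out <- spec
  shift_pt <- function(p) if (is.null(p)) NULL else p + jitter
  out$disc_center <- shift_pt(spec$disc_center)
  out$fovea_center <- shift_pt(spec$fovea_center)
  out$curves <- lapply(spec$curves, function(cv) {
    cv$xy <- sweep(cv$xy, 2, jitter, `+`)
    rng <- apply(cv$xy, 2, range)
    if (rng[1, 1] < 0 || rng[1, 2] < 0 ||
        rng[2, 1] > spec$size_px - 1 || rng[2, 2] > spec$size_px - 1)
      stop("jitter moves a vessel off the canvas")
    cv
  })
  out
}

#' Write a synthetic scene to disk
#'
#' Saves the image (PNG + JSON sidecar), the ground-truth label mask, the
#' binary vessel and fovea masks, and a truth JSON (landmarks + per-curve
#' analytic lengths) under `out_dir`.
#'
#' @param scene result of [generate_scene()].
#' @param out_dir output directory.
#' @return the image path, invisibly.
#' @export
write_scene <- function(scene, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stem <- scene$image$image_id
  img_path <- file.path(out_dir, paste0(stem, ".png"))
  .write_atomic(img_path, function(tmp) png::writePNG(scene$image$pixels, tmp))
  write_sidecar(scene$image, file.path(out_dir, paste0(stem, ".json")))
  write_mask(scene$truth$labels, file.path(out_dir, paste0(stem, "_avod.png")))
  write_mask(scene$truth$vessel, file.path(out_dir, paste0(stem, "_vessel.png")))
  write_mask(scene$truth$fovea_mask, file.path(out_dir, paste0(stem, "_fovea.png")))
  truth <- list(fovea = scene$truth$fovea,
                disc = scene$truth$disc,
                curves = scene$truth$curves)
  .write_atomic(file.path(out_dir, paste0(stem, "_truth.json")), function(tmp)
    jsonlite::write_json(truth, tmp, auto_unbox = TRUE, digits = NA, na = "null"))
  invisible(img_path)
}
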
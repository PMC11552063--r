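# The vascular measurement suite.

fake_segment <- function(arc, width) {
  n <- max(3, round(arc) + 1)
  structure(list(points = cbind(rep(5L, n), seq_len(n)),
                 widths_px = rep(width, n), arc_length_px = arc,
                 chord_length_px = arc, mean_width_px = width),
            class = "vessel_segment")
}

test_that("skeletonization is thin, centered and topology-preserving", {
  bar <- straight_vessel_mask(5, length = 100)
  sk <- skeletonize(bar)
  rows <- unique(which(sk == 1L, arr.ind = TRUE)[, 1])
  expect_length(rows, 1)                       # 1-px center line
  expect_lt(abs(sum(sk) - 100), 8)             # length up to end effects
  expect_equal(sum(skeletonize(matrix(0L, 10, 10))), 0)
  for (s in 1:20) {
    m <- random_stroke_mask(s + 40)
    expect_equal(max(label_components8(skeletonize(m))),
                 max(label_components8(m)))
  }
})

test_that("segment decomposition splits at bifurcations and crossings", {
  line <- straight_vessel_mask(3, length = 120)
  expect_length(vessel_segments(line), 1)
  # symmetric Y: three ~50 px arms
  Y <- matrix(0L, 130, 130)
  Y[65, 15:64] <- 1L
  for (k in 0:35) { Y[65 - k, 65 + k] <- 1L; Y[65 + k, 65 + k] <- 1L }
  segsY <- decompose_segments(Y, min_segment_len = 10)
  expect_length(segsY, 3)
  arcs <- sort(vapply(segsY, `[[`, 0, "arc_length_px"))
  expect_lt(abs(arcs[1] - 50), 4)
  expect_lt(abs(arcs[3] - 35 * sqrt(2)), 4)
  # X crossing: four segments
  X <- matrix(0L, 120, 120)
  for (k in 0:50) { X[35 + k, 10 + k] <- 1L; X[85 - k, 10 + k] <- 1L }
  expect_length(decompose_segments(X, min_segment_len = 10), 4)
  # segments expose ordered paths with arc >= chord
  for (seg in segsY) {
    expect_gte(seg$arc_length_px, seg$chord_length_px - 1e-9)
    expect_equal(nrow(seg$points), length(seg$widths_px))
  }
})

test_that("vessel density is an exact pixel ratio", {
  expect_equal(vessel_density(matrix(1L, 10, 10)), 1)
  expect_equal(vessel_density(matrix(0L, 10, 10)), 0)
  sc <- demo_scene(seed = 31, n_vessel_pairs = 2)
  expect_equal(vessel_density(sc$truth$vessel),
               sum(sc$truth$vessel) / length(sc$truth$vessel))
})

test_that("fractal dimension hits the plane and line limits", {
  sq <- matrix(0L, 512, 512); sq[, ] <- 1L
  fd_sq <- fractal_dimension(sq)
  expect_gte(fd_sq, 1.9); expect_lte(fd_sq, 2.0)
  ln <- matrix(0L, 512, 512); ln[256, ] <- 1L
  fd_ln <- fractal_dimension(ln)
  expect_gte(fd_ln, 0.9); expect_lte(fd_ln, 1.1)
  expect_warning(fd_e <- fractal_dimension(matrix(0L, 64, 64)), "empty")
  expect_true(is.na(fd_e))
  expect_warning(fractal_dimension(matrix(1L, 16, 16)), "grid sizes")
})

test_that("global caliber is the mask-to-skeleton ratio", {
  bar <- straight_vessel_mask(5, length = 400)
  expect_lt(abs(global_caliber(bar) - 5), 0.5)
  thin <- matrix(0L, 20, 60); thin[10, 5:55] <- 1L
  expect_equal(global_caliber(thin), 1)
  expect_equal(global_caliber(thin, scale_um_per_px = 11.71), 11.71)
  expect_true(is.na(global_caliber(matrix(0L, 5, 5))))
})

test_that("local caliber recovers drawn widths and aggregates by length", {
  segs <- vessel_segments(straight_vessel_mask(7, length = 300))
  expect_lt(abs(local_caliber(segs) - 7), 0.5)
  two <- list(fake_segment(50, 4), fake_segment(50, 8))
  expect_equal(local_caliber(two), 6)
  skew <- list(fake_segment(90, 4), fake_segment(10, 8))
  expect_equal(local_caliber(skew), (90 * 4 + 10 * 8) / 100)
  expect_equal(local_caliber(skew, aggregation = "mean"), 6)
  expect_equal(local_caliber(two, scale_um_per_px = 2), 12)
  expect_true(is.na(local_caliber(list())))
})

test_that("tortuosity density is zero for straight, analytic for a semicircle,
           and strictly increasing over a sinusoid amplitude ladder", {
  expect_equal(tortuosity_density(cbind(rep(7, 80), seq_len(80))), 0)
  diagonal <- cbind(seq_len(60), seq_len(60))
  expect_equal(tortuosity_density(diagonal), 0)
  R <- 40
  th <- seq(0, pi, length.out = 400)
  semi <- cbind(R * sin(th), R * cos(th))
  expect_lt(abs(tortuosity_density(semi) - (pi / 2 - 1) / (pi * R)), 1e-4)
  taus <- vapply(c(2, 4, 6, 8, 10), function(a) {
    roi_tortuosity(vessel_segments(
      render_vessel(synth_sinusoid(40, 10, 300, a, 75, 5), c(90, 320))))
  }, 0)
  expect_true(all(diff(taus) > 0))
})

test_that("Knudtson pairing matches the hand-iterated oracle and its algebra", {
  # six equal arteries, worked by hand: 3 x 124.451 -> {154.878, 124.451} -> 174.843
  expect_equal(knudtson_equivalent(rep(100, 6), "artery"), 174.8428, tolerance = 1e-4)
  w <- 37.5
  expect_equal(knudtson_equivalent(c(w, w), "vein"), 0.95 * w * sqrt(2))
  set <- c(110, 95, 80, 120, 70, 100)
  expect_equal(knudtson_equivalent(set, "artery"),
               knudtson_equivalent(sample(set), "artery"))
  for (s in 1:100) {
    ws <- slomorph:::.with_seed(s, runif(6, 40, 160))
    cc <- slomorph:::.with_seed(s + 1000, runif(1, 0.5, 3))
    expect_equal(knudtson_equivalent(cc * ws, "vein"),
                 cc * knudtson_equivalent(ws, "vein"), tolerance = 1e-10)
  }
  expect_error(knudtson_equivalent(c(100, -1), "artery"), "positive")
  expect_true(is.na(knudtson_equivalent(50, "vein")))
})

test_that("CRAE/CRVE segment selection uses the six widest and AVR divides them", {
  segs <- lapply(c(10, 9, 8, 7, 6, 5, 4, 3), fake_segment, arc = 60)
  expect_equal(crae_crve(segs, "artery"),
               knudtson_equivalent(c(10, 9, 8, 7, 6, 5), "artery"))
  expect_warning(cv4 <- crae_crve(segs[1:5], "vein"), "using 4")
  expect_equal(cv4, knudtson_equivalent(c(10, 9, 8, 7), "vein"))
  expect_true(is.na(crae_crve(segs[1], "artery")))
  expect_equal(avr(150, 200), 0.75)
  expect_equal(avr(120, 120), 1)
  expect_true(is.na(avr(NA, 120)))
  expect_error(avr(100, 0), "positive")
})

test_that("a two-branch tree with arteries at 0.8x vein width gives the
           closed-form AVR", {
  canvas <- c(300, 300)
  mk <- function(rows, w, cls) synth_polyline(rows, w, cls)
  veins <- list(mk(rbind(c(100, 20), c(100, 280)), 10, "vein"),
                mk(rbind(c(140, 20), c(140, 280)), 10, "vein"))
  arts <- list(mk(rbind(c(180, 20), c(180, 280)), 8, "artery"),
               mk(rbind(c(220, 20), c(220, 280)), 8, "artery"))
  sc <- generate_scene(synthetic_spec(size_px = 300, curves = c(veins, arts),
                                      noise_sd = 0, seed = 1))
  seg_a <- vessel_segments(sc$truth$artery)
  seg_v <- vessel_segments(sc$truth$vein)
  got <- avr(crae_crve(seg_a, "artery"), crae_crve(seg_v, "vein"))
  expect_lt(abs(got - 0.8 * 0.88 / 0.95) / (0.8 * 0.88 / 0.95), 0.05)
})

test_that("the full metric table follows the metric-to-map assignment", {
  scm <- demo_scene(seed = 41, n_vessel_pairs = 3)
  recm <- analyze_scene_records(scm)
  expect_equal(nrow(recm), 3)
  expect_setequal(recm$roi, "whole")
  expect_true(all(is.finite(recm$fractal_dimension)))
  scd <- demo_scene(seed = 42, location = "disc", n_vessel_pairs = 3)
  recd <- analyze_scene_records(scd)
  expect_equal(nrow(recd), 9)
  zones <- dplyr::filter(recd, roi != "whole")
  expect_true(all(is.na(zones$fractal_dimension)))
  expect_true(all(is.na(zones$vessel_density)))
  expect_true(all(is.na(zones$global_caliber_px)))
  expect_true(all(is.finite(zones$local_caliber_px)))
  # CRAE on artery rows, CRVE on vein rows, AVR on the all-vessel row
  expect_true(all(is.na(dplyr::filter(recd, vessel_class != "artery")$crae_px)))
  expect_true(all(is.na(dplyr::filter(recd, vessel_class != "vein")$crve_px)))
  whole_all <- dplyr::filter(recd, vessel_class == "all", roi == "whole")
  expect_equal(whole_all$avr,
               dplyr::filter(recd, vessel_class == "artery", roi == "whole")$crae_px /
               dplyr::filter(recd, vessel_class == "vein", roi == "whole")$crve_px)
  # micron columns are scale multiples of pixel columns
  expect_equal(recd$local_caliber_um,
               recd$local_caliber_px * recd$scale_um_per_px)
  # determinism: identical inputs give bit-identical rows
  expect_identical(recd, analyze_scene_records(scd))
})
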
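# Mask post-processing and landmark geometry.

test_that("binarize keeps the 0.5 boundary and matches a per-pixel oracle", {
  expect_matrix_equal(binarize(matrix(0.5, 4, 4)), matrix(1L, 4, 4))
  expect_matrix_equal(binarize(matrix(0, 4, 4)), matrix(0L, 4, 4))
  m <- slomorph:::.with_seed(1, matrix(runif(500), 20, 25))
  oracle <- matrix(as.integer(as.vector(m) >= 0.5), 20, 25)
  expect_matrix_equal(binarize(m), oracle)
  expect_error(binarize(matrix(1.5, 2, 2)), "outside")
})

test_that("clean_mask removes sub-threshold blobs, keeps boundary areas, is idempotent", {
  m <- matrix(0L, 40, 40)
  m[2, 2:6] <- 1L                      # 5 px blob
  m[20, 10:19] <- 1L                   # 10 px blob
  out <- clean_mask(m, 10)
  expect_equal(sum(out[2, ]), 0)       # below threshold: removed
  expect_equal(sum(out[20, ]), 10)     # exactly threshold: retained
  expect_matrix_equal(clean_mask(out, 10), out)
  # isolated salt speckle on a synthetic mask is removed exactly
  base <- straight_vessel_mask(5, length = 80)
  noisy <- base
  noisy[cbind(28, seq(5, 100, by = 6))] <- 1L   # isolated single pixels
  expect_matrix_equal(clean_mask(noisy, 10), clean_mask(base, 10))
})

test_that("bridge_gaps joins collinear gaps, refuses perpendicular ones, never splits", {
  v <- straight_vessel_mask(5, length = 200)
  cut <- v; cut[, 105:106] <- 0L       # 2 px gap
  expect_equal(max(label_components8(cut)), 2L)
  joined <- bridge_gaps(cut, 3)
  expect_equal(max(label_components8(joined)), 1L)
  expect_matrix_equal(bridge_gaps(joined, 3), joined)  # idempotent
  # perpendicular endpoints are not joined (angle rule)
  perp <- slomorph:::.as_binary(
    render_vessel(synth_polyline(rbind(c(30, 5), c(30, 50)), 3), c(90, 90)) |
    render_vessel(synth_polyline(rbind(c(35, 53), c(80, 53)), 3), c(90, 90)))
  expect_equal(max(label_components8(perp)),
               max(label_components8(bridge_gaps(perp, 4))))
  expect_equal(max(label_components8(bridge_gaps(perp, 4))), 2L)
})

test_that("component count never increases under bridging (property)", {
  for (s in 1:20) {
    m <- random_stroke_mask(s)
    expect_lte(max(label_components8(bridge_gaps(m, 3))),
               max(label_components8(m)))
  }
})

test_that("post-processing stays within the dilated input support", {
  for (s in 1:5) {
    m <- random_stroke_mask(s + 100)
    out <- bridge_gaps(clean_mask(m, 10), 3)
    grown <- slomorph:::.from_eb(EBImage::dilate(
      slomorph:::.as_eb(m), EBImage::makeBrush(9, shape = "disc")))
    expect_equal(sum(out == 1L & grown == 0), 0)
  }
})

test_that("fovea centroid is the member-pixel mean in 0-based coordinates", {
  m <- matrix(0L, 40, 40)
  m[11:13, 21:23] <- 1L   # rows 10-12, cols 20-22 in 0-based terms
  f <- fovea_centroid(m)
  expect_equal(f$x_px, 21)
  expect_equal(f$y_px, 11)
  expect_true(f$present)
  expect_false(fovea_centroid(matrix(0L, 5, 5))$present)
  disc <- circle_mask(200, 200, 101.3, 88.7, 60)
  f2 <- fovea_centroid(disc)
  expect_lt(abs(f2$x_px - 88.7), 0.5)
  expect_lt(abs(f2$y_px - 101.3), 0.5)
})

test_that("moments ellipse fit recovers circles, ellipses and rotations", {
  circ <- circle_mask(160, 160, 80, 80, 50)
  d <- fit_disc(circ)
  expect_lt(abs(d$diameter_px - 100), 1)
  expect_lt(abs(d$major_px - d$minor_px), 1)
  expect_lt(abs(d$x_px - 80), 0.5)
  ell <- slomorph:::.ellipse_mask(200, 200, 100, 100, 40, 60)  # 80 x 120 axes
  de <- fit_disc(ell)
  expect_lt(abs(de$diameter_px - 100), 1)
  expect_lt(abs(de$major_px - 120), 1.5)
  expect_lt(abs(de$minor_px - 80), 1.5)
  # rotation by 90 degrees swaps axes, keeps D within 1 px
  rot <- t(ell)[ncol(ell):1, ]
  dr <- fit_disc(rot)
  expect_lt(abs(dr$diameter_px - de$diameter_px), 1)
  expect_lt(abs(dr$major_px - de$major_px), 1)
  expect_false(fit_disc(matrix(0L, 8, 8))$present)
})

test_that("laterality/location rules follow the documented decision table", {
  shape <- c(768, 768)
  fov_c <- list(x_px = 384, y_px = 384, present = TRUE)
  disc_left <- list(x_px = 40, y_px = 384, diameter_px = 120, present = TRUE)
  r <- infer_laterality_location(fov_c, disc_left, shape)
  expect_equal(r$laterality, "left")
  expect_equal(r$location, "macula")
  disc_c <- list(x_px = 384, y_px = 384, diameter_px = 120, present = TRUE)
  r2 <- infer_laterality_location(list(present = FALSE), disc_c, shape)
  expect_equal(r2$location, "disc")
  expect_equal(r2$laterality, "unknown")   # dead-center disc: tie -> unknown
  disc_r <- list(x_px = 500, y_px = 384, diameter_px = 120, present = TRUE)
  r3 <- infer_laterality_location(list(present = FALSE), disc_r, shape)
  expect_equal(r3$location, "disc")
  expect_equal(r3$laterality, "right")
  expect_warning(
    r4 <- infer_laterality_location(list(present = FALSE),
                                    list(present = FALSE), shape),
    "landmark")
  expect_equal(r4$location, "unknown")
})

test_that("synthetic scenes infer the generated laterality and location", {
  sc <- demo_scene(seed = 5, n_vessel_pairs = 2)
  f <- fovea_centroid(sc$truth$fovea_mask)
  d <- fit_disc(sc$truth$disc_mask)
  r <- infer_laterality_location(f, d, dim(sc$image$pixels))
  expect_equal(r$laterality, "right")
  expect_equal(r$location, "macula")
})
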
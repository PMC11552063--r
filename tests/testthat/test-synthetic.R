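# Synthetic scene generator: rendering geometry, determinism, analytic
# ground truth.

test_that("rendered vessel area matches the analytic stadium area", {
  cv <- synth_polyline(rbind(c(30, 20), c(30, 119)), 5)
  m <- render_vessel(cv, c(60, 140))
  analytic <- 100 * 5 + pi * 2.5^2   # rectangle + two end half-discs
  expect_lt(abs(sum(m) - analytic) / analytic, 0.05)
  # butt-capped variant has no caps: exactly length x width on the grid
  mb <- straight_vessel_mask(5, length = 100)
  expect_equal(sum(mb), 500)
})

test_that("degenerate and disjoint strokes rasterize as expected", {
  thin <- render_vessel(synth_polyline(rbind(c(20, 5), c(20, 80)), 1), c(40, 90))
  sk <- skeletonize(thin)
  expect_lte(sum(thin) - sum(sk), 4)  # width-1 stroke is its own skeleton up to ends
  two <- slomorph:::.as_binary(
    render_vessel(synth_polyline(rbind(c(20, 5), c(20, 80)), 3), c(60, 90)) |
    render_vessel(synth_polyline(rbind(c(40, 5), c(40, 80)), 3), c(60, 90)))
  expect_equal(max(label_components8(two)), 2L)
  expect_error(render_vessel(synth_polyline(rbind(c(1, 1), c(9, 9)), 0.5),
                             c(20, 20)), "width")
})

test_that("sinusoid analytic arc length agrees with independent quadrature", {
  a <- 7; p <- 90; L <- 300
  cv <- synth_sinusoid(40, 10, L, a, p, 5)
  omega <- 2 * pi / p
  # composite Simpson oracle, independent of stats::integrate
  n <- 20000
  tt <- seq(0, L, length.out = n + 1)
  f <- sqrt(1 + (a * omega)^2 * cos(omega * tt)^2)
  simpson <- (L / n) / 3 * (f[1] + f[n + 1] +
    4 * sum(f[seq(2, n, 2)]) + 2 * sum(f[seq(3, n - 1, 2)]))
  expect_lt(abs(cv$arc_length_px - simpson), 1e-6)
  expect_gte(cv$arc_length_px, cv$chord_length_px)
})

test_that("scene generation is deterministic and ground truth is exact", {
  spec <- random_scene_spec("macula", seed = 7)
  s1 <- generate_scene(spec)
  s2 <- generate_scene(spec)
  expect_identical(s1$image$pixels, s2$image$pixels)
  expect_identical(s1$truth$labels, s2$truth$labels)
  s3 <- generate_scene(random_scene_spec("macula", seed = 8))
  expect_false(identical(s1$image$pixels, s3$image$pixels))
  # ground-truth vessel density is an exact pixel-count ratio
  expect_equal(vessel_density(s1$truth$vessel),
               sum(s1$truth$vessel) / length(s1$truth$vessel))
  # label encoding consistent with binary masks
  expect_true(all(s1$truth$labels %in% 0:4))
  expect_matrix_equal(
    s1$truth$vessel,
    matrix(as.integer(s1$truth$labels %in% 1:3), nrow(s1$truth$labels)))
})

test_that("noise-free vessels are brighter than the local background", {
  spec <- random_scene_spec("disc", seed = 4, noise_sd = 0)
  sc <- generate_scene(spec)
  for (cv in spec$curves) {
    idx <- unique(round(cv$xy)) + 1L     # pixels under the analytic centerline
    centers <- sc$image$pixels[idx]
    expect_true(all(centers > 0.25 + 0.05))  # above background + margin
  }
})

test_that("central light reflex brightens the centerline strip", {
  base <- synthetic_spec(size_px = 128,
                         curves = list(synth_polyline(rbind(c(64, 10), c(64, 117)), 9)),
                         fovea_center = NULL, disc_center = NULL,
                         noise_sd = 0, seed = 1)
  refl <- base; refl$reflex <- TRUE
  i0 <- generate_scene(base)$image$pixels
  i1 <- generate_scene(refl)$image$pixels
  expect_gt(i1[65, 64], i0[65, 64])          # centerline brighter
  expect_equal(i1[64 - 6, 64], i0[64 - 6, 64]) # vessel flank unchanged
})

test_that("repeated pairs share the tree and shift ground truth exactly", {
  spec <- random_scene_spec("macula", seed = 9, n_vessel_pairs = 2)
  pr <- generate_repeated_pair(spec, jitter = c(0, 0))
  expect_identical(pr[[1]]$truth$vessel, pr[[2]]$truth$vessel)
  expect_false(identical(pr[[1]]$image$pixels, pr[[2]]$image$pixels)) # new noise
  pr2 <- generate_repeated_pair(spec, jitter = c(5, 0))
  expect_equal(unname(pr2[[2]]$truth$fovea["y"]),
               unname(pr2[[1]]$truth$fovea["y"]) + 5)
  expect_equal(unname(pr2[[2]]$truth$fovea["x"]),
               unname(pr2[[1]]$truth$fovea["x"]))
  expect_error(generate_repeated_pair(spec, jitter = c(50, 0)), "jitter")
})

test_that("overlapping disc and fovea is rejected", {
  expect_error(
    synthetic_spec(size_px = 256, disc_center = c(128, 128),
                   fovea_center = c(128, 150)),
    "overlap")
})
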
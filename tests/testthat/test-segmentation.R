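# Working-resolution handling, the classical vesselness baseline, and
# segmentation-bundle ingestion.

test_that("resize respects kinds and round-trips label masks accurately", {
  m <- matrix(runif(64), 8, 8)
  expect_identical(resize_to_working(m, c(8, 8), "intensity"), m)
  big <- matrix(runif(1536 * 1536), 1536, 1536)
  small <- resize_to_working(big, kind = "intensity")
  expect_equal(dim(small), c(768L, 768L))
  disc <- circle_mask(768, 768, 380, 390, 60)  # D = 120 >= 100
  down <- resize_to_working(disc, c(384, 384), kind = "label")
  expect_true(all(down %in% c(0L, 1L)))
  up <- resize_to_working(down, c(768, 768), kind = "label")
  expect_gte(dice(up, disc), 0.95)
  expect_error(resize_to_working(m, c(0, 10)), "positive")
})

test_that("vesselness is zero on constant images and 90-degree equivariant", {
  z <- vesselness(matrix(0.4, 64, 64))
  expect_true(all(z == 0))
  sc <- generate_scene(synthetic_spec(
    size_px = 128,
    curves = list(synth_polyline(rbind(c(30, 10), c(100, 117)), 5)),
    noise_sd = 0, seed = 1))
  img <- sc$image$pixels
  rot90 <- function(m) t(m)[ncol(m):1, ]          # counter-clockwise
  unrot90 <- function(m) t(m[nrow(m):1, ])
  v1 <- vesselness(img)
  v2 <- unrot90(vesselness(rot90(img)))
  expect_lt(max(abs(v1 - v2)), 1e-6)
})

test_that("baseline vessel probability segments clean scenes at Dice >= 0.80", {
  sc <- generate_scene(random_scene_spec("macula", seed = 3, noise_sd = 0))
  p <- vessel_probability(sc$image$pixels)
  expect_true(all(p >= 0 & p <= 1))
  expect_gte(dice(binarize(p, 0.5), sc$truth$vessel), 0.80)
})

test_that("baseline fovea detection localizes dips and reports absence", {
  spec <- random_scene_spec("macula", seed = 6, n_vessel_pairs = 2, noise_sd = 0.01)
  spec$fovea_center <- c(384, 300)
  sc <- generate_scene(spec)
  p <- detect_fovea_baseline(sc$image$pixels)
  f <- fovea_centroid(binarize(p, 0.5))
  expect_true(f$present)
  expect_lt(sqrt((f$x_px - 300)^2 + (f$y_px - 384)^2), 15)
  # disc-centered scene without a fovea: peak stays below threshold
  scd <- generate_scene(random_scene_spec("disc", seed = 6, noise_sd = 0.01))
  pd <- detect_fovea_baseline(scd$image$pixels)
  expect_false(fovea_centroid(binarize(pd, 0.5))$present)
})

test_that("the baseline path is deterministic", {
  sc <- demo_scene(seed = 12, n_vessel_pairs = 2)
  b1 <- segment_baseline(sc$image)
  b2 <- segment_baseline(sc$image)
  expect_identical(b1$binary, b2$binary)
  expect_identical(b1$prob, b2$prob)
})

test_that("ingested masks take precedence and unions are harmonized", {
  dir <- withr::local_tempdir()
  sc <- demo_scene(seed = 13, n_vessel_pairs = 2)
  write_scene(sc, dir)
  stem <- sc$image$image_id
  img <- read_slo_image(file.path(dir, paste0(stem, ".png")))
  b <- ingest_bundle(img, list(
    avod = file.path(dir, paste0(stem, "_avod.png")),
    vessel = file.path(dir, paste0(stem, "_vessel.png")),
    fovea = file.path(dir, paste0(stem, "_fovea.png"))))
  expect_equal(b$provenance, "external")
  expect_matrix_equal(b$binary$vessel, sc$truth$vessel)
  expect_matrix_equal(b$binary$fovea, sc$truth$fovea_mask)
  # artery/vein only: all-vessel recomputed as the union
  b2 <- ingest_bundle(img, list(avod = file.path(dir, paste0(stem, "_avod.png"))))
  expect_matrix_equal(b2$binary$vessel,
                      slomorph:::.as_binary(b2$binary$artery | b2$binary$vein))
  # corrected naming flips provenance
  file.copy(file.path(dir, paste0(stem, "_avod.png")),
            file.path(dir, paste0(stem, "_avod_corrected.png")))
  b3 <- ingest_bundle(img, list(avod = file.path(dir, paste0(stem, "_avod_corrected.png"))))
  expect_equal(b3$provenance, "corrected")
  # shape mismatch is an explicit error
  write_mask(matrix(0L, 10, 10), file.path(dir, "tiny.png"))
  expect_error(ingest_bundle(img, list(avod = file.path(dir, "tiny.png"))), "shape")
})
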
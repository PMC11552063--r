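# Agreement, error and reproducibility statistics.

test_that("dice handles identity, disjoint, nested and empty masks", {
  a <- matrix(0L, 10, 10); a[2:6, 2:6] <- 1L
  expect_equal(dice(a, a), 1)
  b <- matrix(0L, 10, 10); b[8:9, 8:9] <- 1L
  expect_equal(dice(a, b), 0)
  big <- matrix(0L, 20, 20); big[1:10, 1:10] <- 1L   # 100 px
  sub <- matrix(0L, 20, 20); sub[1:5, 1:10] <- 1L    # 50 px inside big
  expect_equal(dice(sub, big), 2 * 50 / 150)
  expect_equal(dice(big, sub), dice(sub, big))       # symmetry
  expect_equal(dice(matrix(0L, 4, 4), matrix(0L, 4, 4)), 1)
})

test_that("rank AUC matches exhaustive pair counting and tie conventions", {
  tr <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(auc(matrix(c(0.9, 0.8, 0.3, 0.1), 2, 2), tr), 1)
  expect_equal(auc(matrix(0.7, 2, 2), tr), 0.5)
  expect_equal(auc(tr, tr), 1)
  # one inversion among 4 pos x 4 neg pairs... oracle by brute force
  p <- matrix(c(0.9, 0.2, 0.6, 0.4, 0.8, 0.1, 0.3, 0.05), 2, 4)
  y <- matrix(c(1, 0, 1, 0, 1, 0, 1, 0), 2, 4)
  pos <- p[y == 1]; neg <- p[y == 0]
  oracle <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(auc(p, y), oracle)
  # complement symmetry
  expect_equal(auc(1 - p, 1 - y), auc(p, y))
})

test_that("Bland-Altman closed forms and bias recovery", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(ba0[c("md", "loa_low", "loa_high")]),
               c(md = 0, loa_low = 0, loa_high = 0))
  ba <- bland_altman(c(1, 0), c(0, 1))   # d = {+1, -1}
  expect_equal(ba$md, 0)
  expect_equal(ba$loa_high, 1.96 * sqrt(2))
  x <- slomorph:::.with_seed(3, rnorm(500))
  bias <- 0.7
  bab <- bland_altman(x + bias, x + slomorph:::.with_seed(4, rnorm(500, 0, 0.1)))
  expect_lt(abs(bab$md - bias), 0.05)
})

test_that("ICC(3,1) consistency form: identities, shift invariance, recovery", {
  m <- cbind(c(1, 5, 9, 13), c(1, 5, 9, 13))
  expect_equal(icc31(m)$icc, 1)
  expect_equal(icc31(cbind(m[, 1], m[, 1] + 10))$icc, 1)  # fixed shift ignored
  sim <- simulate_paired_measurements(500, between_sd = 10, within_sd = 1, seed = 7)
  est <- icc31(sim)
  closed <- 10^2 / (10^2 + 1^2)
  expect_lt(abs(est$icc - closed), 0.01)
  expect_lte(est$ci_low, est$icc)
  expect_gte(est$ci_high, est$icc)
})

test_that("lambda noise: optimum, worked example, scale invariance", {
  same <- cbind(c(1, 5, 9), c(1, 5, 9))
  expect_true(all(lambda_noise(same)$lambda_pct == 0))
  # eye means {10, 20, 30} have SD exactly 10; eye 1 pair {9, 11} has SD sqrt(2)
  m <- rbind(c(9, 11), c(20, 20), c(30, 30))
  lam <- lambda_noise(m)
  expect_equal(lam$lambda_pct[1], 100 * sqrt(2) / 10, tolerance = 1e-9)
  expect_equal(lam$lambda_pct[2:3], c(0, 0))
  sc <- lambda_noise(m * 37.5)
  expect_equal(sc$lambda_pct, lam$lambda_pct, tolerance = 1e-9)
  expect_error(lambda_noise(cbind(c(1, 1), c(1, 1))), "between-eye")
})

test_that("lambda and ICC jointly recover a known within/between ratio", {
  sim <- simulate_paired_measurements(200, between_sd = 8, within_sd = 2, seed = 11)
  lam <- lambda_noise(sim)
  expect_lt(abs(median(lam$lambda_pct) - 25), 3)
  expect_lt(abs(icc31(sim)$icc - 1 / (1 + 0.25^2)), 0.02)
})

test_that("MAE, diagonal combination and unit conversions", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(2, -1), c(1, 2)), 2)
  x <- slomorph:::.with_seed(5, rnorm(50)); y <- slomorph:::.with_seed(6, rnorm(50))
  expect_equal(mae(x, y), mean(abs(x - y)))
  expect_equal(combine_axis_mae(3, 4), 5)
  expect_equal(combine_axis_mae(0, 2.5), 2.5)
  expect_equal(round(combine_axis_mae(6.28, 4.78), 1), 7.9)
  expect_lt(abs(field_scale_um_per_px(9, 768) - 11.71), 0.01)
  expect_equal(field_scale_um_per_px(9, 768), 9000 / 768)
  expect_equal(px_to_um(5, 11.71), 58.55)
  expect_equal(px_to_um(0, 11.71), 0)
  expect_equal(px2_to_mm2(638.17, 11.71875), 638.17 * (11.71875e-3)^2)
  expect_lt(abs(px2_to_mm2(638.17, 11.71875) - 0.0876), 5e-4)
})

test_that("repro_report collates statistics and exposes tidy/glance/autoplot", {
  sim <- simulate_paired_measurements(60, between_sd = 5, within_sd = 1,
                                      mu = 100, seed = 21)
  rep <- repro_report(sim[, 1], sim[, 2], metric = "local_caliber", units = "um")
  expect_s3_class(rep, "slo_repro")
  expect_gt(rep$pearson, 0.9)
  expect_lte(rep$bland_altman$loa_low, rep$bland_altman$md)
  expect_gte(rep$bland_altman$loa_high, rep$bland_altman$md)
  td <- tidy(rep)
  expect_true(all(c("icc31", "lambda_median_pct") %in% td$statistic))
  gl <- glance(rep)
  expect_equal(gl$n_eyes, 60)
  plt <- autoplot(rep)
  expect_s3_class(plt, "ggplot")
  expect_s3_class(plot_lambda(list(rep)), "ggplot")
})
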
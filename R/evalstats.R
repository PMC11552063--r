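# Validation statistics: segmentation agreement (Dice, AUC), error metrics
# (MAE, diagonal combination, unit conversions) and reproducibility analysis
# of repeated measurements (Bland-Altman, ICC(3,1), eye-level
# measurement-noise lambda).

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty
#' (identical masks, avoids 0/0).
#'
#' @param a,b binary matrices of the same shape.
#' @return value in [0, 1].
#' @export
dice <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  a <- .as_binary(a); b <- .as_binary(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney AUC over pixels with midranks for ties: the probability
#' that a random foreground pixel scores above a random background pixel.
#'
#' @param prob numeric matrix of scores in [0, 1].
#' @param truth binary matrix; both classes must be present.
#' @return AUC in [0, 1].
#' @export
auc <- function(prob, truth) {
  stopifnot(all(dim(prob) == dim(truth)))
  y <- as.vector(.as_binary(truth))
  p <- as.vector(prob)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes present in truth")
  r <- rank(p)  # midranks for ties
  (sum(r[y == 1L]) - as.numeric(n1) * (n1 + 1) / 2) / (as.numeric(n1) * n0)
}

#' Mean absolute error
#' @param pred,truth numeric vectors of equal length.
#' @return mean of `|pred - truth|`.
#' @export
mae <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) >= 1)
  mean(abs(pred - truth))
}

#' Combine per-axis MAEs into a diagonal error
#'
#' Euclidean combination `sqrt(mae_x^2 + mae_y^2)` of the horizontal and
#' vertical coordinate errors into a single diagonal pixel error.
#'
#' @param mae_x,mae_y non-negative per-axis errors.
#' @return diagonal error, same units.
#' @export
combine_axis_mae <- function(mae_x, mae_y) {
  stopifnot(mae_x >= 0, mae_y >= 0)
  sqrt(mae_x^2 + mae_y^2)
}

#' Pixel/physical unit conversions
#'
#' `px_to_um` converts a length using the microns-per-pixel scale;
#' `px2_to_mm2` converts an area in square pixels to square millimetres;
#' `field_scale_um_per_px` gives the sampling scale of a field of view
#' (e.g. a 9 mm, 30-degree field over 768 px is 11.71 um/px).
#'
#' @param value_px length in pixels.
#' @param scale_um_per_px microns per pixel (> 0).
#' @return converted value.
#' @export
px_to_um <- function(value_px, scale_um_per_px) {
  stopifnot(scale_um_per_px > 0)
  value_px * scale_um_per_px
}

#' @rdname px_to_um
#' @param area_px2 area in square pixels.
#' @export
px2_to_mm2 <- function(area_px2, scale_um_per_px) {
  stopifnot(scale_um_per_px > 0)
  area_px2 * (scale_um_per_px * 1e-3)^2
}

#' @rdname px_to_um
#' @param field_mm field of view extent in millimetres.
#' @param n_px pixels across the field.
#' @export
field_scale_um_per_px <- function(field_mm, n_px) {
  stopifnot(field_mm > 0, n_px > 0)
  field_mm * 1000 / n_px
}

#' Bland-Altman analysis of paired measurements
#'
#' Differences `d = m1 - m2`; mean difference MD and limits of agreement
#' `MD +/- 1.96 * sd(d)` (sample standard deviation, n - 1).
#'
#' @param m1,m2 paired measurement vectors (>= 2 pairs).
#' @return list with `md`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(m1, m2) {
  stopifnot(length(m1) == length(m2), length(m1) >= 2)
  d <- m1 - m2
  s <- stats::sd(d)
  if (!is.finite(s)) s <- 0
  list(md = mean(d), loa_low = mean(d) - 1.96 * s,
       loa_high = mean(d) + 1.96 * s, sd_diff = s, n = length(d))
}

#' Intraclass correlation ICC(3,1)
#'
#' Two-way mixed-effects, single-measure, consistency ICC from the
#' subject x measurement ANOVA:
#' `(BMS - EMS) / (BMS + (k - 1) EMS)`
#' with BMS the between-subject and EMS the residual mean square. The 95%
#' confidence interval uses the standard F-distribution bounds. The
#' consistency form is invariant to a fixed shift of one measurement; an
#' absolute-agreement variant `ICC(3,k)`-style absolute form is available
#' via `type = "agreement"` (two-way mixed, single measure, absolute).
#'
#' @param measurements numeric matrix, one row per subject (eye), one
#'   column per repeated measurement (>= 3 subjects, >= 2 measurements).
#' @param type `"consistency"` (default) or `"agreement"`.
#' @param conf_level confidence level for the interval.
#' @return list with `icc`, `ci_low`, `ci_high`, `n`, `k`.
#' @export
icc31 <- function(measurements, type = c("consistency", "agreement"),
                  conf_level = 0.95) {
  type <- match.arg(type)
  x <- as.matrix(measurements)
  n <- nrow(x); k <- ncol(x)
  stopifnot(n >= 3, k >= 2, all(is.finite(x)))
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  bms <- k * sum((row_m - grand)^2) / (n - 1)
  jms <- n * sum((col_m - grand)^2) / (k - 1)
  resid <- x - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand
  ems <- sum(resid^2) / ((n - 1) * (k - 1))
  if (bms + (k - 1) * ems < 1e-300) return(list(icc = NA_real_, ci_low = NA_real_,
                                                ci_high = NA_real_, n = n, k = k))
  icc <- if (type == "consistency") {
    (bms - ems) / (bms + (k - 1) * ems)
  } else {
    (bms - ems) / (bms + (k - 1) * ems + k * (jms - ems) / n)
  }
  # F-based CI (consistency form)
  alpha <- 1 - conf_level
  if (ems <= 0) {
    ci <- c(NA_real_, NA_real_)
  } else {
    f <- bms / ems
    fl <- f / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- f * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }
  list(icc = icc, ci_low = ci[1], ci_high = ci[2], n = n, k = k)
}

#' Eye-level measurement-noise lambda
#'
#' Per eye: the standard deviation of that eye's repeated measurements
#' divided by the standard deviation of eye-level mean measurements across
#' the population, expressed as a percentage (0 is optimal). Returned as
#' the per-eye distribution; scale-invariant (multiplying every measurement
#' by a constant leaves lambda unchanged).
#'
#' @param measurements numeric matrix, one row per eye, one column per
#'   repeat (>= 2 eyes, >= 2 repeats).
#' @return tibble with `eye`, `lambda_pct`.
#' @export
lambda_noise <- function(measurements) {
  x <- as.matrix(measurements)
  stopifnot(nrow(x) >= 2, ncol(x) >= 2)
  between <- stats::sd(rowMeans(x))
  if (!is.finite(between) || between <= 0)
    stop("between-eye standard deviation is zero; lambda undefined")
  within <- apply(x, 1, stats::sd)
  tibble::tibble(eye = seq_len(nrow(x)), lambda_pct = 100 * within / between)
}

#' Reproducibility report for one metric
#'
#' Collates the population reproducibility statistics for a set of paired
#' (repeated, unregistered) measurements of one metric: MAE between passes,
#' Pearson and Spearman correlations, ICC(3,1) with 95% CI, Bland-Altman
#' mean difference and limits of agreement, and the per-eye lambda noise
#' distribution.
#'
#' @param m1,m2 paired measurement vectors (one value per eye).
#' @param metric name of the metric.
#' @param units unit string (e.g. `"um"`, `"px"`, `""`).
#' @return an object of class `slo_repro`.
#' @export
repro_report <- function(m1, m2, metric = "metric", units = "") {
  stopifnot(length(m1) == length(m2), length(m1) >= 3)
  ba <- bland_altman(m1, m2)
  icc <- icc31(cbind(m1, m2))
  lam <- lambda_noise(cbind(m1, m2))
  structure(list(
    metric = metric, units = units, n_eyes = length(m1),
    mae = mae(m1, m2),
    pearson = stats::cor(m1, m2, method = "pearson"),
    spearman = stats::cor(m1, m2, method = "spearman"),
    icc = icc, bland_altman = ba, lambda = lam,
    pairs = tibble::tibble(eye = seq_along(m1), m1 = m1, m2 = m2)),
    class = "slo_repro")
}

#' @export
print.slo_repro <- function(x, ...) {
  cat(sprintf("<slo_repro> %s (%s), %d eyes\n", x$metric,
              ifelse(nzchar(x$units), x$units, "unitless"), x$n_eyes))
  cat(sprintf("  MAE %.4g | Pearson %.3f | Spearman %.3f | ICC(3,1) %.3f [%.3f, %.3f]\n",
              x$mae, x$pearson, x$spearman,
              x$icc$icc, x$icc$ci_low, x$icc$ci_high))
  cat(sprintf("  Bland-Altman MD %.4g, LoA [%.4g, %.4g]\n",
              x$bland_altman$md, x$bland_altman$loa_low, x$bland_altman$loa_high))
  cat(sprintf("  lambda median %.1f%% (IQR %.1f-%.1f%%)\n",
              stats::median(x$lambda$lambda_pct),
              stats::quantile(x$lambda$lambda_pct, 0.25),
              stats::quantile(x$lambda$lambda_pct, 0.75)))
  invisible(x)
}

#' @export
tidy.slo_repro <- function(x, ...) {
  tibble::tibble(
    metric = x$metric,
    statistic = c("mae", "pearson", "spearman", "icc31", "icc31_ci_low",
                  "icc31_ci_high", "ba_md", "ba_loa_low", "ba_loa_high",
                  "lambda_median_pct", "lambda_iqr_low_pct", "lambda_iqr_high_pct"),
    value = c(x$mae, x$pearson, x$spearman, x$icc$icc, x$icc$ci_low,
              x$icc$ci_high, x$bland_altman$md, x$bland_altman$loa_low,
              x$bland_altman$loa_high,
              stats::median(x$lambda$lambda_pct),
              unname(stats::quantile(x$lambda$lambda_pct, c(0.25, 0.75)))))
}

#' @export
glance.slo_repro <- function(x, ...) {
  tibble::tibble(metric = x$metric, units = x$units, n_eyes = x$n_eyes,
                 mae = x$mae, pearson = x$pearson, spearman = x$spearman,
                 icc31 = x$icc$icc, ba_md = x$bland_altman$md,
                 lambda_median_pct = stats::median(x$lambda$lambda_pct))
}

#' Simulate paired eye-level measurements with a fixed noise ratio
#'
#' Draws eye-level true means from `N(mu, between_sd^2)` and produces two
#' repeats per eye as `mean +/- within_sd / sqrt(2)` with random sign
#' order, so every eye's within-eye sample standard deviation equals
#' `within_sd` exactly and the within/between noise ratio is a property of
#' each eye rather than an expectation. Used for parameter-recovery checks
#' of the lambda and ICC estimators.
#'
#' @param n_eyes number of eyes.
#' @param between_sd population SD of eye-level means.
#' @param within_sd within-eye repeat SD.
#' @param mu population mean.
#' @param seed RNG seed.
#' @return matrix with `n_eyes` rows and 2 columns.
#' @export
simulate_paired_measurements <- function(n_eyes, between_sd, within_sd,
                                         mu = 0, seed = 1L) {
  .with_seed(seed, {
    means <- stats::rnorm(n_eyes, mu, between_sd)
    sgn <- sample(c(-1, 1), n_eyes, replace = TRUE)
    off <- within_sd / sqrt(2)
    cbind(means + sgn * off, means - sgn * off)
  })
}
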
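# ggplot2 figures for reproducibility results.

#' Bland-Altman plot of a reproducibility report
#'
#' Differences between passes against pair means, with the mean difference
#' and 95% limits of agreement as horizontal references.
#'
#' @param object an `slo_repro` (see [repro_report()]).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.slo_repro <- function(object, ...) {
  d <- dplyr::mutate(object$pairs,
                     avg = (.data$m1 + .data$m2) / 2,
                     diff = .data$m1 - .data$m2)
  ba <- object$bland_altman
  ggplot2::ggplot(d, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = ba$md, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high), linetype = 2) +
    ggplot2::labs(
      title = sprintf("Bland-Altman: %s", object$metric),
      x = sprintf("Pair mean%s", ifelse(nzchar(object$units),
                                        paste0(" (", object$units, ")"), "")),
      y = "Difference (pass 1 - pass 2)") +
    ggplot2::theme_minimal()
}

#' Box plot of eye-level measurement-noise lambda
#'
#' @param reports list of `slo_repro` objects (one per metric).
#' @param ref_pct reference line percentage (drawn dashed).
#' @return a ggplot object.
#' @export
plot_lambda <- function(reports, ref_pct = 25) {
  d <- dplyr::bind_rows(lapply(reports, function(r)
    dplyr::mutate(r$lambda, metric = r$metric)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$lambda_pct)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::geom_hline(yintercept = ref_pct, linetype = 2) +
    ggplot2::labs(x = NULL, y = "Eye-level measurement noise λ (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 .data
NULL
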
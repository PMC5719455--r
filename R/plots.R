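# ggplot2 displays for the main result types.

#' Forest-style plot of per-SNP log odds ratios
#'
#' SNPs ordered by log OR with 95% CI bars; positive values indicate a
#' higher risk-allele burden in the first population of the contrast.
#'
#' @param object an `or_table` from [snp_log_or_table()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot or_table
#' @export
autoplot.or_table <- function(object, ...) {
  df <- as_tibble(object)
  df$rank <- rank(df$log_or, ties.method = "first")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$log_or)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_linerange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high,
                   colour = .data$significant), alpha = 0.6
    ) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(
      x = "SNP (ordered by log OR)", y = "log odds ratio (A vs B)",
      colour = "95% CI excludes 0"
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of a resampling null distribution
#'
#' @param object a `null_distribution` from [bootstrap_meta()] or
#'   [random_snpset_null()].
#' @param bins histogram bins.
#' @param ... unused.
#' @return a ggplot object with the observed value marked.
#' @method autoplot null_distribution
#' @export
autoplot.null_distribution <- function(object, bins = 60, ...) {
  df <- tibble(value = object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(
      x = "replicate pooled log OR", y = "replicates",
      title = sprintf("%s null (z = %.2f, p = %.2g)",
                      object$kind, object$z_test$z, object$z_test$p)
    ) +
    ggplot2::theme_minimal()
}

#' Box plots of polygenic-score distributions by population
#'
#' @param object a `prs_result` from [polygenic_risk_score()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot prs_result
#' @export
autoplot.prs_result <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), !is.na(.data$score))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$population, y = .data$score,
                                   fill = .data$population)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "polygenic risk score") +
    ggplot2::theme_minimal()
}

#' Scatter of PRS against an ancestry fraction with decile boxes
#'
#' @param object an `ancestry_regression` from [ancestry_prs_regression()].
#' @param ... unused.
#' @return a ggplot object with the least-squares line and per-decile
#'   interquartile boxes.
#' @method autoplot ancestry_regression
#' @export
autoplot.ancestry_regression <- function(object, ...) {
  dat <- object$data
  dec <- object$deciles
  dec$mid <- (dec$fraction_min + dec$fraction_max) / 2
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fraction, y = .data$score)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_rect(
      data = dec, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$fraction_min, xmax = .data$fraction_max,
                   ymin = .data$prs_q25, ymax = .data$prs_q75),
      fill = NA, colour = "grey30"
    ) +
    ggplot2::geom_segment(
      data = dec, inherit.aes = FALSE,
      ggplot2::aes(x = .data$fraction_min, xend = .data$fraction_max,
                   y = .data$prs_median, yend = .data$prs_median),
      colour = "grey30"
    ) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "blue") +
    ggplot2::labs(
      x = paste(object$ancestry, "ancestry fraction"),
      y = "polygenic risk score",
      title = sprintf("r = %.2f, p = %.2g, n = %d",
                      object$pearson_r, object$p_value, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' MDS scatter of samples coloured by population
#'
#' @param coords tibble from [project_mds()].
#' @param populations optional tibble (sample, population) for colouring.
#' @return a ggplot object.
#' @export
plot_mds <- function(coords, populations = NULL) {
  df <- coords
  if (!is.null(populations)) {
    df <- dplyr::left_join(df, populations, by = "sample")
  } else {
    df$population <- "all"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$MDS1, y = .data$MDS2,
                                   colour = .data$population)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "dimension 1", y = "dimension 2") +
    ggplot2::theme_minimal()
}
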
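#' Plot a cohort comparison table
#'
#' Group means with SD error bars per variable, annotated with the test used
#' and significance.
#'
#' @param comparisons Tibble from [compare_cohort()].
#' @param variables Optional subset of variables to draw.
#' @return A ggplot.
#' @export
plot_cohort_comparison <- function(comparisons, variables = NULL) {
  d <- comparisons
  if (!is.null(variables)) d <- dplyr::filter(d, .data$variable %in% variables)
  long <- dplyr::bind_rows(
    dplyr::transmute(d, variable = .data$variable, group = "control",
                     mean = .data$mean_x, sd = .data$sd_x,
                     significant = .data$significant),
    dplyr::transmute(d, variable = .data$variable, group = "case",
                     mean = .data$mean_y, sd = .data$sd_y,
                     significant = .data$significant)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$group, .data$mean, fill = .data$group)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.2
    ) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "group mean ± SD") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
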
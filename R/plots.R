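# ggplot2 helpers for the main result types.

#' @describeIn metagene_profile Line plot of the metagene profile with the
#'   anchor codon marked.
#' @param object An `rt_metagene` tibble.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.rt_metagene <- function(object, ...) {
  anchor <- attr(object, "anchor") %||% "anchor"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position,
                                       y = .data$fraction)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(
      x = paste0("P-site position relative to ", anchor, " codon (nt)"),
      y = "fraction of footprints"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn group_median_shifts Tile heatmap of median shifts; larger
#'   tiles mark significant Wilcoxon tests, as in the conventional display.
#' @param object An `rt_shifts` tibble (rows from one or more features).
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.rt_shifts <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$level, y = .data$feature)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$delta_median,
                                    height = ifelse(.data$significant,
                                                    0.95, 0.55),
                                    width = ifelse(.data$significant,
                                                   0.95, 0.55))) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = "median shift\n(log2 RE)") +
    ggplot2::theme_minimal()
}

#' @describeIn high_low_enrichment Tile heatmap of log2 enrichment ratios;
#'   grey tiles mark zero observations.
#' @param object An `rt_enrichment` tibble.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.rt_enrichment <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$level, y = .data$feature)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$log2_ratio)) +
    ggplot2::geom_tile(data = object[object$zero_observation, , drop = FALSE],
                       fill = "grey70") +
    ggplot2::facet_wrap(~ .data$group) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  na.value = "grey70") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2(group / reference)") +
    ggplot2::theme_minimal()
}

#' Dot plot of permutation feature importance
#'
#' @param fit An `rt_rf` object with importance computed.
#' @param top_n Show the `top_n` highest-ranked features (default 25).
#' @return A ggplot object.
#' @export
plot_importance <- function(fit, top_n = 25) {
  imp <- tidy(fit) %>% head(top_n)
  ggplot2::ggplot(imp, ggplot2::aes(
    x = .data$importance,
    y = stats::reorder(.data$feature, .data$importance)
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$importance - .data$sd,
      xmax = .data$importance + .data$sd
    ), height = 0.2, colour = "grey50") +
    ggplot2::labs(x = unique(imp$metric), y = NULL) +
    ggplot2::theme_minimal()
}
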
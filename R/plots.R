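# Static plot layer over the pipeline's tables. Each function returns a
# ggplot object; blank (white) cells mark sparse or empty correlograms.

#' Heatmap of one shape metric over all pairs of a region
#'
#' N x N tile map with reference units on the x axis and comparison units
#' on the y axis; sparse/empty correlograms are left blank (white), so a
#' silent unit shows as a white row and column. The area-left-of-zero map
#' of any region satisfies cell(i, j) = 1 - cell(j, i).
#'
#' @param metrics data.frame from [shapeMetrics()].
#' @param region analysis-region index to plot.
#' @param metric one of \code{"uniform"}, \code{"p_value"},
#'   \code{"peak_count"}, \code{"area_left"}.
#' @return a ggplot object.
#' @export
plotMetricHeatmap <- function(metrics, region,
                              metric = c("area_left", "uniform", "p_value",
                                         "peak_count")) {
  metric <- match.arg(metric)
  df <- metrics[metrics$region == region, , drop = FALSE]
  if (!nrow(df)) stop("no metrics for region ", region)
  df$value <- df[[metric]]
  df$value[df$sparse] <- NA
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ref_id, y = .data$cmp_id,
                                        fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "reference unit", y = "comparison unit",
                  fill = metric,
                  title = sprintf("%s, analysis region %d", metric, region)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  if (metric == "area_left") {
    g <- g + ggplot2::scale_fill_gradient2(midpoint = 0.5, low = "blue",
                                           mid = "green", high = "red",
                                           limits = c(0, 1),
                                           na.value = "white")
  } else {
    g <- g + ggplot2::scale_fill_viridis_c(na.value = "white")
  }
  g
}

#' Metric distributions across analysis regions
#'
#' Violin of one metric per region with the individual correlogram values
#' jittered on top, so the reader can judge whether the violin shape is
#' supported by enough points to be trusted.
#'
#' @param metrics data.frame from [shapeMetrics()] covering >= 1 region.
#' @param metric metric column to plot.
#' @return a ggplot object.
#' @export
plotMetricDistributions <- function(metrics, metric = "area_left") {
  df <- metrics[!metrics$sparse & !is.na(metrics[[metric]]), , drop = FALSE]
  df$value <- df[[metric]]
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$region),
                                   y = .data$value)) +
    ggplot2::geom_violin(fill = "grey85", colour = "grey40", scale = "width") +
    ggplot2::geom_jitter(width = 0.15, size = 0.4, alpha = 0.4) +
    ggplot2::labs(x = "analysis region", y = metric) +
    ggplot2::theme_minimal()
}

#' Class-fraction time courses
#'
#' One line per class per scheme: the fraction of correlograms carrying
#' each classification, across analysis regions.
#'
#' @param fractions data.frame from the pipeline (scheme-bound
#'   [classFractions()] tables).
#' @return a ggplot object.
#' @export
plotClassFractions <- function(fractions) {
  ggplot2::ggplot(fractions,
                  ggplot2::aes(x = .data$region, y = .data$fraction,
                               colour = .data$class)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~scheme, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "analysis region", y = "fraction of correlograms") +
    ggplot2::theme_minimal()
}

#' Transition-probability matrices
#'
#' Tile map of P(class in region r | class in region r-1), one facet per
#' grouping (region step or period).
#'
#' @param transitions data.frame from [transitionProbabilities()].
#' @return a ggplot object.
#' @export
plotTransitionMatrix <- function(transitions) {
  ggplot2::ggplot(transitions,
                  ggplot2::aes(x = .data$to_class, y = .data$from_class,
                               fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~grouping) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "white") +
    ggplot2::labs(x = "class in region r", y = "class in region r-1") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Combined classification heatmap
#'
#' Percent of correlograms in each uniformity x leader/follower x
#' peak-count cell, one facet per grouping; empty cells are blank.
#'
#' @param combos data.frame from [combinedComboTable()].
#' @return a ggplot object.
#' @export
plotComboHeatmap <- function(combos) {
  df <- combos
  df$percent[df$n == 0] <- NA
  df$col <- paste(df$uniformity_class, df$peak_class, sep = "\n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$peak_class, y = .data$lf_class,
                                   fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(uniformity_class ~ grouping) +
    ggplot2::scale_fill_gradient(low = "darkblue", high = "darkred",
                                 na.value = "white") +
    ggplot2::labs(x = "peak-count class", y = "leader/follower class",
                  fill = "% of correlograms") +
    ggplot2::theme_minimal()
}
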
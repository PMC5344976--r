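#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a contact matrix
#'
#' @param object A `contact_matrix`.
#' @param log2_scale Colour by log2(value + 1) (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot contact_matrix
#' @export
autoplot.contact_matrix <- function(object, log2_scale = TRUE, ...) {
  df <- tidy(object, keep_zeros = TRUE)
  df <- dplyr::bind_rows(df, dplyr::rename(df[df$bin_i != df$bin_j, ],
                                           bin_i = "bin_j", bin_j = "bin_i"))
  if (log2_scale) df$value <- log2(df$value + 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_i, y = .data$bin_j, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = if (log2_scale) "log2(1+x)" else "value") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "bin", y = "bin",
                  title = sprintf("%s contact map (%d bins)", object$state, n_bins(object))) +
    ggplot2::theme_minimal()
}

#' Domain segmentation along the genome
#'
#' Bars span each domain; height is the relative interaction density, fill
#' encodes border confidence (the smaller of the domain's two border
#' scores), and the horizontal line at 1 marks the distance-expected level.
#'
#' @param object A `domain_segmentation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot domain_segmentation
#' @export
autoplot.domain_segmentation <- function(object, ...) {
  df <- tidy(object)
  df$conf_pair <- pmin(df$confidence, c(df$confidence[-1], df$confidence[1]))
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start_bp / 1e3, xmax = .data$end_bp / 1e3,
                                    ymin = 0, ymax = .data$density, fill = .data$conf_pair)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_fill_viridis_c(name = "border\nconfidence", limits = c(1, 10)) +
    ggplot2::labs(x = "genome position (kb)", y = "relative interaction density",
                  title = sprintf("%d chromosome interaction domains", nrow(df))) +
    ggplot2::theme_minimal()
}

#' Projected view of a model ensemble
#'
#' Draws the x-y projection of every model as faint paths and the
#' lowest-penalty model (or cluster centroids, when clustered) on top.
#'
#' @param object A `model_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot model_ensemble
#' @export
autoplot.model_ensemble <- function(object, ...) {
  df <- tidy(object)
  hi <- if (!is.null(object$centroids)) object$centroids else which.min(object$penalty)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, group = .data$model)) +
    ggplot2::geom_path(alpha = 0.05) +
    ggplot2::geom_path(data = df[df$model %in% hi, ],
                       ggplot2::aes(colour = .data$particle), linewidth = 1) +
    ggplot2::scale_colour_viridis_c(name = "particle") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
  p
}

#' Co-expression versus distance curves
#'
#' @param stratified Result of [distance_stratified_coexpression()].
#' @return A ggplot object.
#' @export
plot_coexpression_distance <- function(stratified) {
  ggplot2::ggplot(stratified$curves,
                  ggplot2::aes(x = .data$distance / 1e3, y = .data$mean_abs_coexpression,
                               colour = .data$stratum)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "genomic distance (kb)", y = "mean |co-expression|") +
    ggplot2::theme_minimal()
}

#' Null distribution of a permutation test
#'
#' @param result A `permutation_result`.
#' @return A ggplot object.
#' @export
plot_permutation_null <- function(result) {
  ggplot2::ggplot(tidy(result), ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = result$observed, colour = "red") +
    ggplot2::labs(x = "null statistic", y = "count",
                  title = sprintf("observed %.3g, p = %.3g (%s)",
                                  result$observed, result$p_value, result$side)) +
    ggplot2::theme_minimal()
}
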
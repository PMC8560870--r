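#' Marker heat map
#'
#' Heat map of the marker table in the layout used for visual class
#' comparison: one row per wavelet-packet node (ordered by level and
#' nominal band), epochs across the horizontal axis, one facet per
#' modality x class. Values are z-scored per modality so the two
#' modalities' colour scales are comparable.
#'
#' @param features Wide feature tibble from [extract_features()].
#' @return A ggplot object.
#' @export
plot_feature_heatmap <- function(features) {
  meta <- intersect(c("participant", "class", "epoch", "modality", "roi",
                      "config"), names(features))
  long <- tidyr::pivot_longer(features, !dplyr::any_of(meta),
                              names_to = "node", values_to = "value")
  long <- dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(long, .data$modality),
    value = as.numeric(scale(.data$value))
  ))
  bands <- node_bands(unique(long$node))
  node_order <- bands$path[order(bands$level, bands$band_low)]
  long$node <- factor(long$node, levels = node_order)
  long <- dplyr::arrange(long, .data$class, .data$participant, .data$epoch)
  long <- dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(long, .data$modality, .data$node, .data$class),
    col = dplyr::row_number()
  ))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$col, y = .data$node,
                                     fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_grid(modality ~ class) +
    ggplot2::scale_fill_viridis_c(name = "z") +
    ggplot2::labs(x = "epoch (concatenated across participants)",
                  y = "wavelet-packet node") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Box plot of per-repetition cross-validation accuracies
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cv_result <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$accuracy)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_hline(yintercept = 1 / 3, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(title = paste("Cross-validation:", object$scheme),
                  x = NULL, y = "accuracy") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' ROI scan bar plot
#'
#' @param scan Tibble from [roi_scan()].
#' @return A ggplot object.
#' @export
plot_roi_scan <- function(scan) {
  scan$roi <- factor(scan$roi, levels = ROI_IDS)
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$roi, y = .data$mean_accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1 / 3, linetype = "dashed") +
    ggplot2::labs(x = "region of interest", y = "mean fused accuracy") +
    ggplot2::theme_minimal()
}
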
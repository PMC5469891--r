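## ggplot2 views: 1D metric traces, the 2D LF-HF scatter, and decision
## regions.

#' Plot univariate stress-metric traces over time
#'
#' One panel per metric, with labeled scenario spans shaded -- the classic
#' 1D view whose ambiguities the 2D representation resolves.
#'
#' @param features A feature tibble from [window_features()].
#' @param metrics Feature columns to show.
#' @return A ggplot object.
#' @export
plot_feature_traces <- function(features,
                                metrics = c("LFp_ms2", "HFp_ms2", "ratio_p",
                                            "LFiA_ms", "HFiA_ms")) {
  long <- tidyr::pivot_longer(features, dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric, levels = metrics)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_center_s, y = .data$value,
                                     colour = .data$label)) +
    ggplot2::geom_line(ggplot2::aes(group = 1), colour = "grey60",
                       linewidth = 0.3) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "window center (s)", y = NULL, colour = "scenario") +
    ggplot2::theme_minimal()
}

#' 2D LF-HF scatter plot
#'
#' Each analysis window becomes one point in the LF-HF plane; scenarios
#' occupy distinctive regions, which is what makes categorization
#' possible.
#'
#' @param features A feature tibble.
#' @param x,y Feature columns for the two axes.
#' @return A ggplot object.
#' @export
plot_lf_hf_scatter <- function(features, x = "LFiA_ms", y = "HFiA_ms") {
  ggplot2::ggplot(features,
                  ggplot2::aes(x = .data[[x]], y = .data[[y]],
                               colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(colour = "scenario") +
    ggplot2::theme_minimal()
}

#' @method autoplot hrv_categorizer
#' @export
autoplot.hrv_categorizer <- function(object, resolution = 150, ...) {
  if (object$mode != "2d")
    abort("decision-region plots need a 2D categorizer")
  dm <- decision_map(object, resolution = resolution)
  fx <- object$features[1]
  fy <- object$features[2]
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = dm,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      fill = .data$label),
                         alpha = 0.25) +
    ggplot2::geom_point(data = object$training,
                        ggplot2::aes(x = .data[[fx]], y = .data[[fy]],
                                     colour = .data[[object$label_col]])) +
    ggplot2::labs(x = fx, y = fy, fill = "region", colour = "scenario") +
    ggplot2::theme_minimal()
}

#' @method autoplot part1_study
#' @export
autoplot.part1_study <- function(object, ...) {
  autoplot(object$models[["2D_iA"]], ...)
}
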
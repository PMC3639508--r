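#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fusion-event histogram with an optional bi-exponential fit
#'
#' @param object A `vk_event_histogram`.
#' @param fit Optional `vk_biexp_fit` overlaid as a curve.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vk_event_histogram <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object$bins, ggplot2::aes(x = .data$bin_mid, y = .data$prob)) +
    ggplot2::geom_col(width = 1, fill = "grey70", colour = "grey40") +
    ggplot2::labs(x = "time after Ca2+ arrival (s)",
                  y = "fraction of fusion events per 1-s bin") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    tt <- seq(0, max(object$bins$bin_right), length.out = 400)
    curve <- tibble::tibble(t = tt, y = biexp_f(tt, fit))
    p <- p + ggplot2::geom_line(data = curve,
                                ggplot2::aes(x = .data$t, y = .data$y),
                                colour = "black", linewidth = 0.8)
  }
  p
}

#' @rdname autoplot.vk_event_histogram
#' @param x A `vk_biexp_fit`.
#' @export
autoplot.vk_biexp_fit <- function(object, ...) {
  tt <- seq(min(object$data$t), max(object$data$t), length.out = 400)
  curve <- tibble::tibble(t = tt, y = biexp_f(tt, object))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t, y = .data$y)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(data = curve, colour = "black") +
    ggplot2::labs(x = "time (s)", y = "event fraction") +
    ggplot2::theme_minimal()
}

#' Plot the cumulative fusion distribution
#'
#' @param hist A `vk_event_histogram`.
#' @return A ggplot.
#' @export
plot_cumulative <- function(hist) {
  cum <- cumulative_distribution(hist)
  ggplot2::ggplot(cum, ggplot2::aes(x = .data$t_s, y = .data$cumulative)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time after Ca2+ arrival (s)",
                  y = "cumulative fraction of fusion events") +
    ggplot2::theme_minimal()
}

#' Plot a spot-intensity histogram on the a.u. scale
#'
#' Marks the single/cluster classification thresholds.
#'
#' @param spots Spot tibble with `intensity_au`.
#' @param params [classifier_params()].
#' @param binwidth Histogram bin width in a.u. (default 0.1).
#' @return A ggplot.
#' @export
plot_intensity_histogram <- function(spots, params = classifier_params(),
                                     binwidth = 0.1) {
  ggplot2::ggplot(spots, ggplot2::aes(x = .data$intensity_au)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey70",
                            colour = "grey40", boundary = 0) +
    ggplot2::geom_vline(xintercept = c(params$single_max_au,
                                       params$cluster_min_au,
                                       params$cluster_range_max_au),
                        linetype = "dashed") +
    ggplot2::labs(x = "spot intensity (a.u., single-vesicle mode = 1)",
                  y = "spots") +
    ggplot2::theme_minimal()
}

#' Bar plot of per-condition clustering counts with significance stars
#'
#' @param report A `vk_clustering_report`.
#' @return A ggplot (mean +/- SD over imaging locations).
#' @export
plot_condition_counts <- function(report) {
  fc <- report$field_counts
  fc$condition <- factor(fc$condition, levels = fc$condition)
  stars <- if (!is.null(report$comparisons)) {
    merge <- dplyr::left_join(fc,
      dplyr::select(report$comparisons, condition = "condition_a", "stars"),
      by = "condition")
    merge$stars
  } else rep(NA_character_, nrow(fc))
  fc$stars <- ifelse(is.na(stars) | stars == "ns", "", stars)
  ggplot2::ggplot(fc, ggplot2::aes(x = .data$condition, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.25) +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars,
                                    y = .data$mean + .data$sd),
                       vjust = -0.5) +
    ggplot2::labs(x = NULL, y = "DiI spots per imaging location") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
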
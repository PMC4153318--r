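#' Plot an aligned metric timeline
#'
#' Binned mean with a SEM ribbon against time relative to the threshold
#' crossing, the standard visualization of step-like thalamic recruitment.
#'
#' @param object An `aligned_timeline` from [align_timeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aligned_timeline <- function(object, ...) {
  b <- object$bins |>
    mutate(mid = (.data$bin_start_min + .data$bin_end_min) / 2)
  ggplot2::ggplot(b, ggplot2::aes(x = .data$mid, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25, na.rm = TRUE) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time relative to crossing (min)",
                  y = "metric (binned mean ± SEM)") +
    ggplot2::theme_minimal()
}

#' Plot a distance-binned correlation profile
#'
#' @param object A `spatial_profile` from [spatial_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spatial_profile <- function(object, ...) {
  b <- as_tibble(object) |>
    filter(.data$n_pairs > 0) |>
    mutate(mid = (.data$bin_start_um + .data$bin_end_um) / 2)
  ggplot2::ggplot(b, ggplot2::aes(x = .data$mid, y = .data$mean_r)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_r - .data$sem_r,
                                        ymax = .data$mean_r + .data$sem_r),
                           width = 20, na.rm = TRUE) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "intersomatic distance (µm)",
                  y = "pairwise correlation (mean ± SEM)") +
    ggplot2::theme_minimal()
}

#' Scatter of cortical vs thalamic discharge intensities
#'
#' @param pairs Tibble from [intensity_pairs()].
#' @return A ggplot object.
#' @export
plot_intensity_pairs <- function(pairs) {
  ggplot2::ggplot(pairs,
                  ggplot2::aes(x = .data$cortical_fraction,
                               y = .data$thalamic_auc_mv_s)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "grey40") +
    ggplot2::labs(x = "cortical intensity (fraction of ever-active cells)",
                  y = "thalamic intensity (AUC, mV·s)") +
    ggplot2::theme_minimal()
}
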
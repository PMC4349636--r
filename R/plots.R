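#' Two-channel droplet scatter plot
#'
#' The standard droplet-intensity view: each droplet at its
#' (channel 1, channel 2) amplitude, optionally overlaid with the fitted
#' positivity thresholds; droplets are colored by the four classes the
#' thresholds induce.
#'
#' @param amplitudes Amplitude tibble or a `drop_phase_sim`.
#' @param thresholds Optional [channel_thresholds()] to overlay.
#' @param alpha Point transparency.
#' @return A ggplot object.
#' @export
plot_droplets <- function(amplitudes, thresholds = NULL, alpha = 0.25) {
  if (inherits(amplitudes, "drop_phase_sim")) amplitudes <- amplitudes$amplitudes
  p <- ggplot2::ggplot(amplitudes,
                       ggplot2::aes(x = .data$ch2_amplitude,
                                    y = .data$ch1_amplitude))
  if (!is.null(thresholds)) {
    calls <- droplet_calls(amplitudes, thresholds)
    cls <- dplyr::case_when(
      calls$ch1_positive & calls$ch2_positive ~ "double positive",
      calls$ch1_positive ~ "ch1 only",
      calls$ch2_positive ~ "ch2 only",
      TRUE ~ "double negative")
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = cls), alpha = alpha,
                                 size = 0.4) +
      ggplot2::geom_hline(yintercept = thresholds$ch1, linetype = 2) +
      ggplot2::geom_vline(xintercept = thresholds$ch2, linetype = 2) +
      ggplot2::labs(colour = "class")
  } else {
    p <- p + ggplot2::geom_point(alpha = alpha, size = 0.4)
  }
  p + ggplot2::labs(x = "Ch2 amplitude (HEX)", y = "Ch1 amplitude (FAM)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.drop_phase_sim <- function(object, thresholds = NULL, ...) {
  plot_droplets(object$amplitudes, thresholds = thresholds, ...) +
    ggplot2::ggtitle(sprintf("well %s: duplex %s, d = %s kb, true %%linkage %.1f%%",
                             object$config$well_id, object$config$assay$duplex,
                             format(object$config$distance_kb),
                             object$truth$percent_linkage))
}

#' @exportS3Method ggplot2::autoplot
autoplot.fragment_survival_fit <- function(object, ...) {
  grid <- tibble::tibble(
    distance_kb = seq(0, max(object$data$distance_kb) * 1.05, length.out = 200))
  grid$percent_linkage <- predict_percent_linkage(object$L_kb, grid$distance_kb)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$distance_kb,
                               y = .data$percent_linkage)) +
    ggplot2::geom_line(data = grid, colour = "black") +
    ggplot2::geom_point(colour = "#2166ac", size = 2) +
    ggplot2::labs(x = "genomic distance (kb)", y = "% linkage",
                  title = sprintf("fragment survival: L = %.1f kb (R² = %.3f)",
                                  object$L_kb, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Percent linkage versus distance for a measured series
#'
#' @param series A series tibble (e.g. from [run_milemarker_suite()])
#'   with `distance_kb`, `percent_linkage`, optional `is_control`,
#'   `ci_low`, `ci_high`.
#' @param fit Optional `fragment_survival_fit` whose curve to overlay.
#' @return A ggplot object.
#' @export
plot_distance_series <- function(series, fit = NULL) {
  if (!"is_control" %in% names(series)) series$is_control <- FALSE
  p <- ggplot2::ggplot(series,
                       ggplot2::aes(x = .data$distance_kb,
                                    y = .data$percent_linkage,
                                    colour = .data$is_control))
  if (!is.null(fit)) {
    grid <- tibble::tibble(
      distance_kb = seq(0, max(series$distance_kb[is.finite(series$distance_kb)]) * 1.05,
                        length.out = 200),
      is_control = FALSE)
    grid$percent_linkage <- predict_percent_linkage(fit$L_kb, grid$distance_kb)
    p <- p + ggplot2::geom_line(data = grid, colour = "black")
  }
  if (all(c("ci_low", "ci_high") %in% names(series))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high), width = 2)
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "#2166ac",
                                            `TRUE` = "#b2182b"),
                                 labels = c(`FALSE` = "linked pair",
                                            `TRUE` = "cross-chromosome control"),
                                 name = NULL) +
    ggplot2::labs(x = "genomic distance (kb)", y = "% linkage") +
    ggplot2::theme_minimal()
}
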
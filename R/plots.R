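#' Violin plot of jackknife peak-time distributions
#'
#' One violin per unit showing the delete-d jackknife distribution of its
#' peak expression time, with the full-data peak marked by a point and the
#' confidence bounds by bars.
#'
#' @param object A `diel_peaks` tibble from [estimate_peaks()] with
#'   jackknife results.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diel_peaks <- function(object, ...) {
  sp <- subsample_peaks(object)
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$peak_h, y = .data$unit_id)) +
    ggplot2::geom_violin(scale = "width", fill = "grey85", colour = NA) +
    ggplot2::geom_point(
      data = object,
      ggplot2::aes(x = .data$t_peak_h, y = .data$unit_id),
      colour = "red", size = 1.5
    ) +
    ggplot2::geom_errorbarh(
      data = object,
      ggplot2::aes(xmin = .data$ci_low_h, xmax = .data$ci_high_h,
                   y = .data$unit_id),
      inherit.aes = FALSE, height = 0.3
    ) +
    ggplot2::labs(x = "Peak expression time (h)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Box plot of peak times by temporal class
#'
#' @param object A `diel_classes` tibble from [classify_peaks()].
#' @param anchor_h Linearization anchor passed to [anchor_times()];
#'   the axis is relabelled back to clock hours.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diel_classes <- function(object, anchor_h = 6, ...) {
  cl <- dplyr::filter(object, .data$temporal_class != "unclassified")
  cl$temporal_class <- factor(cl$temporal_class,
                              levels = c("early", "middle", "late"))
  cl$anchored <- anchor_times(cl$t_peak_h, anchor_h)
  ggplot2::ggplot(cl, ggplot2::aes(x = .data$temporal_class,
                                   y = .data$anchored)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, height = 0) +
    ggplot2::labs(x = NULL,
                  y = sprintf("Peak time (h after %02.0f:00)", anchor_h)) +
    ggplot2::theme_minimal()
}

#' Plot a count series with its fitted harmonic
#'
#' Relative abundances over time with the fitted sinusoidal rate curve and
#' shaded night periods.
#'
#' @param fit A `harmonic_fit` from [fit_harmonic_poisson()].
#' @param design Optional [diel_design()] supplying night windows.
#' @return A ggplot object.
#' @export
plot_harmonic_fit <- function(fit, design = NULL) {
  df <- tibble::tibble(time_h = fit$times,
                       rel = fit$counts / fit$totals)
  grid <- tibble::tibble(time_h = seq(min(fit$times), max(fit$times),
                                      length.out = 400))
  w <- 2 * pi / fit$period_h
  grid$rel <- exp(fit$coef[1] + fit$coef[2] * cos(w * grid$time_h) +
                    fit$coef[3] * sin(w * grid$time_h))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$rel))
  if (!is.null(design)) {
    nw <- night_windows(design)
    p <- p + ggplot2::geom_rect(
      data = nw,
      ggplot2::aes(xmin = .data$night_start_h, xmax = .data$night_end_h),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "grey80", alpha = 0.5
    )
  }
  p +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "Time (h since midnight, day 1)",
                  y = "Relative transcript abundance") +
    ggplot2::theme_minimal()
}
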
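#' Plot an extracted ion chromatogram
#'
#' @param xic A tibble with `rt` and `intensity` (from [extract_xic()]).
#' @param peaks Optional peak table from [detect_peaks()]; integration
#'   bounds are shaded and apexes marked.
#' @return A ggplot object.
#' @export
plot_xic <- function(xic, peaks = NULL) {
  p <- ggplot2::ggplot(xic, ggplot2::aes(x = .data$rt, y = .data$intensity)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "Retention time (min)", y = "Intensity") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p +
      ggplot2::geom_rect(
        data = peaks, inherit.aes = FALSE,
        ggplot2::aes(xmin = .data$left_rt, xmax = .data$right_rt,
                     ymin = 0, ymax = .data$height),
        fill = "steelblue", alpha = 0.2
      ) +
      ggplot2::geom_point(
        data = peaks, inherit.aes = FALSE,
        ggplot2::aes(x = .data$apex_rt, y = .data$height),
        colour = "steelblue"
      )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a calibration fit
#'
#' Points with the fitted line; the subtitle reports R^2, LOD and LOQ.
#'
#' @param object A `calibration_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calibration_fit <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$concentration, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "Concentration (ng/uL)", y = "Response ratio",
      subtitle = sprintf("R² = %.4f, LOD = %.3g, LOQ = %.3g ng/uL",
                         object$r_squared, object$lod, object$loq)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a relative-abundance profile
#'
#' Bar chart of percent relative abundance (mean across replicates) with
#' standard-deviation error bars.
#'
#' @param profile The `profile` tibble from [relative_abundance()].
#' @return A ggplot object.
#' @export
plot_profile <- function(profile) {
  profile <- profile |>
    mutate(species = stats::reorder(.data$species, -.data$pct_mean))
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$species, y = .data$pct_mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$pct_mean - .data$pct_sd,
                   ymax = .data$pct_mean + .data$pct_sd),
      width = 0.3, na.rm = TRUE
    ) +
    ggplot2::labs(x = NULL, y = "% relative abundance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
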
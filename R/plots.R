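#' Plot a Kaplan-Meier estimate
#'
#' @param object a [km_estimate()] tibble.
#' @param ... unused.
#' @return a ggplot: survival step curves (one per group when present).
#' @method autoplot km_estimate
#' @export
autoplot.km_estimate <- function(object, ...) {
  p <- if ("group" %in% names(object)) {
    ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$surv,
                                         colour = .data$group))
  } else {
    ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$surv))
  }
  p +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the cut-point search profile
#'
#' @param object a [optimal_cutpoint()] result.
#' @param ... unused.
#' @return a ggplot of the log-rank chi-square over candidate cuts, with
#'   the selected cut marked.
#' @method autoplot cutpoint_result
#' @export
autoplot.cutpoint_result <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(.data$cutoff, .data$chi_square)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = 2) +
    ggplot2::labs(
      x = object$feature_name, y = "Log-rank chi-square",
      title = sprintf("Maximally selected cut: %s = %.4g",
                      object$feature_name, object$cutoff),
      subtitle = "Maximum of a scanned statistic; validate on held-out data."
    ) +
    ggplot2::theme_minimal()
}

#' Plot a slide: regions and nuclei
#'
#' @param nuclei tibble from [nuclei_table()].
#' @param regions an [analysis_regions()] object.
#' @return a ggplot with the region rasters underneath the nucleus
#'   centroids (y axis flipped to image convention).
#' @export
plot_slide <- function(nuclei, regions) {
  stopifnot(inherits(regions, "analysis_regions"))
  lab <- matrix("background", nrow(regions$tumour_eff),
                ncol(regions$tumour_eff))
  lab[regions$other] <- "other tissue"
  lab[regions$tas] <- "TAS"
  lab[regions$tumour_eff] <- "tumour"
  grid <- tidyr::expand_grid(
    y = seq_len(nrow(lab)) - 1,
    x = seq_len(ncol(lab)) - 1
  )
  grid$region <- as.vector(t(lab))
  ggplot2::ggplot() +
    ggplot2::geom_raster(
      data = dplyr::filter(grid, .data$region != "background"),
      ggplot2::aes(.data$x, .data$y, fill = .data$region), alpha = 0.5
    ) +
    ggplot2::geom_point(
      data = nuclei,
      ggplot2::aes(.data$x, .data$y, colour = .data$nucleus_type),
      size = 0.6
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  fill = "region", colour = "nucleus") +
    ggplot2::theme_minimal()
}
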
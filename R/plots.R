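#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted aging trajectory with its 95% band
#'
#' Draws the fitted median curve and the `mu +/- 3b` population band of a
#' single trajectory fit.
#'
#' @param object A `laplace_fit`.
#' @param ages Age grid; default 1-year steps over the fit domain.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot laplace_fit
#' @export
autoplot.laplace_fit <- function(object, ages = NULL, ...) {
  dom <- object$basis$domain
  if (is.null(ages)) ages <- seq(dom[1], dom[2], by = 1)
  p <- predict(object, ages)
  ggplot2::ggplot(p, ggplot2::aes(x = .data$age)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower95, ymax = .data$upper95),
      fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$location),
                       colour = "steelblue") +
    ggplot2::labs(x = "Age (years)",
                  y = paste0(object$volume_col,
                             if (object$log_volume) " (log volume)"
                             else " (volume)"),
                  title = "Laplace location-scale aging trajectory",
                  subtitle = "Band: median ± 3 scales (95% of the population)") +
    ggplot2::theme_minimal()
}

#' Plot group trajectories for one or more ROIs
#'
#' Overlays the fitted median curves of every race-by-sex group, with
#' dashed 95% bands, facetted by ROI.
#'
#' @param fits Output of [fit_trajectories()].
#' @param rois ROIs to include; default all.
#' @param ages Age grid; default 1-year steps over the fit domain.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(fits, rois = NULL, ages = NULL) {
  if (is.null(rois)) rois <- unique(fits$roi)
  fr <- fits[fits$roi %in% rois, ]
  dom <- fr$fit[[1]]$basis$domain
  if (is.null(ages)) ages <- seq(dom[1], dom[2], by = 1)
  curves <- purrr::pmap_dfr(fr, function(...) {
    row <- list(...)
    p <- predict(row$fit, ages)
    p$roi <- row$roi
    p$race <- row$race
    p$sex <- row$sex
    p
  })
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$age, colour = .data$race,
                               linetype = .data$sex)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$location)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$lower95), alpha = 0.4,
                       linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$upper95), alpha = 0.4,
                       linewidth = 0.3) +
    ggplot2::facet_wrap(~roi, scales = "free_y") +
    ggplot2::labs(x = "Age (years)", y = "Volume",
                  colour = "Race", linetype = "Sex") +
    ggplot2::theme_minimal()
}

#' Plot effect-size curves across age
#'
#' @param curves Output of [effect_size_curves()].
#' @return A ggplot object.
#' @export
plot_effect_sizes <- function(curves) {
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$age, y = .data$d,
                               colour = paste(.data$group1, "vs",
                                              .data$group2))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~roi, scales = "free_y") +
    ggplot2::labs(x = "Age (years)", y = "Effect size d",
                  colour = "Group pair") +
    ggplot2::theme_minimal()
}
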
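## ggplot2 displays for the main result types.

#' Plot a final diversity map
#'
#' Tile map of the composed (optimized) surface; observed cells can be
#' outlined to show the provenance split.
#'
#' @param object A `final_map`.
#' @param outline_observed Outline cells carrying observed estimates.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.final_map <- function(object, outline_observed = TRUE, ...) {
  stopifnot(all(c("x", "y") %in% names(object)))
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_viridis_c(name = "effective\nspecies") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (outline_observed) {
    p <- p + ggplot2::geom_tile(
      data = object[object$provenance == "observed", , drop = FALSE],
      fill = NA, colour = "grey20", linewidth = 0.2
    )
  }
  p
}

#' Plot an empirical variogram with an optional fitted model
#'
#' @param object An `empirical_variogram`.
#' @param model Optional `variogram_model` whose curve is overlaid.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.empirical_variogram <- function(object, model = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$gamma)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.7) +
    ggplot2::scale_size_area(name = "pairs", max_size = 4) +
    ggplot2::labs(x = "lag distance", y = "semivariance") +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    h <- seq(1e-9, max(object$lag), length.out = 200)
    curve <- tibble::tibble(lag = h, gamma = vg_semivariance(model, h))
    p <- p + ggplot2::geom_line(data = curve, colour = "firebrick")
  }
  p
}

#' Plot held-out predictions of a cross-validation report
#'
#' Observed versus predicted values, one panel per method, with the 1:1
#' line.
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_report <- function(object, ...) {
  ggplot2::ggplot(
    object$predictions,
    ggplot2::aes(x = .data$observed, y = .data$predicted)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(
      x = sprintf("observed %s", object$response),
      y = "held-out prediction"
    ) +
    ggplot2::theme_minimal()
}
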
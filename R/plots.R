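## ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Diagnostic diagram of an isopleth curve
#'
#' Areal increment per isoline level with the site-capture fraction overlaid
#' -- the diagram on which the optimally describing isoline is read off.
#'
#' @param object `isopleth_curve` (possibly annotated by [select_odi()]).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot isopleth_curve
#' @export
autoplot.isopleth_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$level_km)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$delta_area_km2),
                      fill = "grey60", width = diff(object$level_km[1:2]) * 0.85) +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$capture * max(object$delta_area_km2)),
      colour = "firebrick", na.rm = TRUE
    ) +
    ggplot2::scale_y_continuous(
      "areal increment (km²)",
      sec.axis = ggplot2::sec_axis(~ . / max(object$delta_area_km2),
                                   name = "site capture")
    ) +
    ggplot2::labs(x = "LEC radius level (km)") +
    ggplot2::theme_minimal()
  if ("selected" %in% names(object) && any(object$selected)) {
    p <- p + ggplot2::geom_vline(xintercept = object$level_km[object$selected],
                                 linetype = "dashed")
  }
  p
}

#' Map of a Core Area delineation
#'
#' Interpolated LEC surface with sites and the selected Core Area outline for
#' one calibration region of a [build_core_areas()] result.
#'
#' @param x `core_area_set`.
#' @param region region name (default: first).
#' @param sites optional site tibble to overlay.
#' @param ... unused.
#' @return a ggplot.
#' @export
plot_core_areas <- function(x, region = NULL, sites = NULL, ...) {
  if (is.null(region)) region <- names(x$regions)[1]
  r <- x$regions[[region]]
  g <- r$grid
  df <- expand.grid(x = g$x / 1000, y = g$y / 1000)
  df$radius_km <- as.vector(g$z)
  p <- ggplot2::ggplot(df[!is.na(df$radius_km), ],
                       ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$radius_km)) +
    ggplot2::scale_fill_viridis_c(direction = -1, name = "LEC radius (km)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)",
                  title = paste0("Core Areas: ", region)) +
    ggplot2::theme_minimal()
  for (ring in r$polygons) {
    p <- p + ggplot2::geom_path(
      data = data.frame(x = ring[, 1] / 1000, y = ring[, 2] / 1000),
      colour = "black"
    )
  }
  if (!is.null(sites)) {
    p <- p + ggplot2::geom_point(
      data = data.frame(x = sites$x / 1000, y = sites$y / 1000),
      size = 0.5, colour = "white"
    )
  }
  p
}

#' Population estimates per region with quartile bracketing
#'
#' @param object `cologne_estimate`.
#' @param ... unused.
#' @return a ggplot: Q2 people per region with Q1/Q3 whiskers.
#' @method autoplot cologne_estimate
#' @export
autoplot.cologne_estimate <- function(object, ...) {
  r <- object$rows
  ggplot2::ggplot(r, ggplot2::aes(x = stats::reorder(.data$region,
                                                     .data$n_people_q2))) +
    ggplot2::geom_pointrange(ggplot2::aes(y = .data$n_people_q2,
                                          ymin = .data$n_people_q3,
                                          ymax = .data$n_people_q1)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "people (Q2; whiskers Q3–Q1)") +
    ggplot2::theme_minimal()
}
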
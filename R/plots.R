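#' Plot trajectories or path segments
#'
#' Draws the x-y path, one colour per segment (or per individual when no
#' `segment_id` column is present), with the arena outline and the excluded
#' wall margin if an [arena_config()] is supplied.
#'
#' @param data Tibble with `x_cm`, `y_cm` and optionally `segment_id` /
#'   `individual_id`.
#' @param arena Optional [arena_config()] used to draw the arena and margin.
#' @return A ggplot object.
#' @export
plot_paths <- function(data, arena = NULL) {
  d <- as_tibble(data)
  grp <- if ("segment_id" %in% names(d)) "segment_id"
         else if ("individual_id" %in% names(d)) "individual_id"
         else NULL
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x_cm, y = .data$y_cm))
  if (!is.null(arena)) {
    m <- arena$margin_cm
    p <- p +
      ggplot2::annotate("rect", xmin = 0, xmax = arena$width_cm,
                        ymin = 0, ymax = arena$height_cm,
                        fill = NA, colour = "grey30") +
      ggplot2::annotate("rect", xmin = m, xmax = arena$width_cm - m,
                        ymin = m, ymax = arena$height_cm - m,
                        fill = NA, colour = "grey60", linetype = 2)
  }
  if (is.null(grp)) {
    p <- p + ggplot2::geom_path(linewidth = 0.3)
  } else {
    p <- p + ggplot2::geom_path(
      ggplot2::aes(group = .data[[grp]], colour = .data[[grp]]),
      linewidth = 0.3, show.legend = FALSE)
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)")
}

#' Rose diagram of turning angles
#'
#' Histogram of turning angles on a circular axis, optionally split by a
#' grouping column.
#'
#' @param data Tibble with a `theta_deg` column.
#' @param group Optional name of a grouping column for facets.
#' @param binwidth_deg Bin width in degrees.
#' @return A ggplot object.
#' @export
plot_turning_angles <- function(data, group = NULL, binwidth_deg = 15) {
  d <- as_tibble(data)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$theta_deg)) +
    ggplot2::geom_histogram(binwidth = binwidth_deg, boundary = -180,
                            fill = "steelblue", colour = "grey20",
                            linewidth = 0.2) +
    ggplot2::coord_polar(start = pi) +
    ggplot2::scale_x_continuous(limits = c(-180, 180),
                                breaks = seq(-180, 135, by = 45)) +
    ggplot2::labs(x = "turning angle (deg)", y = "count")
  if (!is.null(group)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data[[group]]))
  }
  p
}
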
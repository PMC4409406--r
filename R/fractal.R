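#' Divider (ruler) configuration for fractal path analysis
#'
#' The divider method measures a path with rulers of decreasing length
#' `delta`; for a fractal path the measured length follows
#' `L(delta) = k * delta^(1 - D)`, so `D` is recovered from the log-log
#' slope. Divider sizes are log-spaced between `delta_min_cm` and
#' `delta_max_cm`. The defaults span half an Asellus body size (0.25 cm) to
#' the 100-cm observation scale with 200 divider sizes.
#'
#' @param delta_min_cm,delta_max_cm Smallest and largest divider size, cm.
#' @param n_dividers Number of log-spaced divider sizes (>= 10).
#' @return A `divider_config` object.
#' @export
divider_config <- function(delta_min_cm = 0.25, delta_max_cm = 100,
                           n_dividers = 200) {
  assert_number(delta_min_cm, "delta_min_cm", lower = 1e-12)
  assert_number(delta_max_cm, "delta_max_cm", lower = 1e-12)
  if (delta_min_cm >= delta_max_cm) {
    abort("`delta_min_cm` must be smaller than `delta_max_cm`")
  }
  n_dividers <- assert_count(n_dividers, "n_dividers", lower = 10L)
  structure(list(delta_min_cm = delta_min_cm, delta_max_cm = delta_max_cm,
                 n_dividers = n_dividers),
            class = "divider_config")
}

divider_deltas <- function(config) {
  exp(seq(log(config$delta_min_cm), log(config$delta_max_cm),
          length.out = config$n_dividers))
}

#' Divider configuration adapted to a path's own extent
#'
#' When the 100-cm observation scale is not meaningful (short synthetic
#' paths), the largest divider defaults to half the path's bounding-box
#' diagonal.
#'
#' @param segment Tibble with `x_cm`, `y_cm`.
#' @inheritParams divider_config
#' @export
divider_config_for_path <- function(segment, delta_min_cm = 0.25,
                                    n_dividers = 200) {
  s <- as_tibble(segment)
  diag <- sqrt(diff(range(s$x_cm))^2 + diff(range(s$y_cm))^2)
  divider_config(delta_min_cm, max(diag / 2, delta_min_cm * 10), n_dividers)
}

#' Measure a path with a single divider size
#'
#' Walks the polyline from its first point: each divider step lands on the
#' exact (linearly interpolated) point of the polyline whose straight-line
#' distance from the current anchor equals `delta_cm`. The measured length
#' is the number of full steps times `delta_cm` plus the straight-line
#' remainder from the last anchor to the final point, so a straight path
#' measures its true length at every divider size.
#'
#' @param segment Tibble with `x_cm`, `y_cm` (>= 2 points).
#' @param delta_cm Divider size, cm (> 0).
#' @param reverse Walk the path from its last point instead.
#' @return One-row tibble: `delta_cm`, `L_cm`, `n_steps`.
#' @export
divider_length <- function(segment, delta_cm, reverse = FALSE) {
  s <- as_tibble(segment)
  if (nrow(s) < 2L) abort("`segment` needs at least 2 points")
  assert_number(delta_cm, "delta_cm", lower = 1e-300)
  x <- s$x_cm; y <- s$y_cm
  if (reverse) { x <- rev(x); y <- rev(y) }
  w <- divider_walk_cpp(x, y, delta_cm)
  if (w$n_steps == 0) {
    abort("path is shorter than `delta_cm`: no full divider step fits")
  }
  tibble(delta_cm = delta_cm, L_cm = w$n_steps * delta_cm + w$remainder,
         n_steps = w$n_steps)
}

# vectorised internal version: NA where no full step fits
divider_lengths_all <- function(x, y, deltas) {
  fwd <- map(deltas, function(d) divider_walk_cpp(x, y, d))
  bwd <- map(deltas, function(d) divider_walk_cpp(rev(x), rev(y), d))
  Lf <- vapply(seq_along(deltas), function(i) {
    w <- fwd[[i]]
    if (w$n_steps == 0) NA_real_ else w$n_steps * deltas[i] + w$remainder
  }, numeric(1))
  Lb <- vapply(seq_along(deltas), function(i) {
    w <- bwd[[i]]
    if (w$n_steps == 0) NA_real_ else w$n_steps * deltas[i] + w$remainder
  }, numeric(1))
  tibble(delta_cm = deltas, L_forward_cm = Lf, L_backward_cm = Lb,
         L_cm = (Lf + Lb) / 2)
}

#' Divider-method fractal dimension of a path segment
#'
#' For each log-spaced divider size the path length is measured in both
#' traversal directions and averaged; ordinary least squares of `log L` on
#' `log delta` over all divider sizes with a defined measurement gives the
#' slope `s`, and `D = 1 - s`. `D` is 1 for a straight line and approaches 2
#' for plane-filling (Brownian) motion. Divider sizes too large for the path
#' (no full step fits in either direction) are dropped from the regression.
#'
#' @param segment Tibble with `x_cm`, `y_cm` (>= 5 points; shorter paths are
#'   excluded from fractal analysis for a robust regression).
#' @param config A [divider_config()]; `NULL` uses
#'   [divider_config_for_path()].
#' @return A `fractal_estimate` object holding `D`, the intercept scale `k`,
#'   `r_squared`, `n_deltas_used`, the config, and the per-delta
#'   measurements; see [tidy()], [glance()] and [autoplot()] methods.
#' @export
fractal_mean <- function(segment, config = NULL) {
  s <- as_tibble(segment)
  if (nrow(s) < 5L) {
    abort("`segment` has fewer than 5 locations; excluded from fractal analysis")
  }
  if (is.null(config)) config <- divider_config_for_path(s)
  stopifnot(inherits(config, "divider_config"))
  deltas <- divider_deltas(config)
  meas <- divider_lengths_all(s$x_cm, s$y_cm, deltas)
  used <- !is.na(meas$L_cm) & meas$L_cm > 0
  if (sum(used) < 10L) {
    abort("fewer than 10 divider sizes yield a defined length measurement")
  }
  fit <- lm(log(L_cm) ~ log(delta_cm), data = meas[used, ])
  slope <- unname(coef(fit)[2])
  D <- 1 - slope
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((log(meas$L_cm[used]) - mean(log(meas$L_cm[used])))^2)
  r2 <- if (ss_tot > 1e-20) 1 - ss_res / ss_tot else NA_real_
  if (!is.na(D) && D < 0.95) {
    warn(sprintf("estimated D = %.3f is below 1 beyond estimator noise", D))
  }
  structure(
    list(D = D, k = exp(unname(coef(fit)[1])), r_squared = r2,
         n_deltas_used = sum(used), config = config,
         measurements = mutate(meas, used = used)),
    class = "fractal_estimate")
}

#' @export
print.fractal_estimate <- function(x, ...) {
  cat(sprintf("Divider-method fractal dimension\n  D = %.4f (k = %.3g, r^2 = %.4f, %d divider sizes used)\n",
              x$D, x$k, x$r_squared, x$n_deltas_used))
  invisible(x)
}

#' @describeIn fractal_mean Per-divider-size measurement table.
#' @param x A `fractal_estimate` object.
#' @param ... Unused.
#' @export
tidy.fractal_estimate <- function(x, ...) x$measurements

#' @describeIn fractal_mean One-row estimate summary.
#' @export
glance.fractal_estimate <- function(x, ...) {
  tibble(D = x$D, k = x$k, r_squared = x$r_squared,
         n_deltas_used = x$n_deltas_used,
         delta_min_cm = x$config$delta_min_cm,
         delta_max_cm = x$config$delta_max_cm)
}

#' @describeIn fractal_mean Log-log plot of measured length against divider
#'   size with the fitted power law.
#' @param object A `fractal_estimate` object.
#' @export
autoplot.fractal_estimate <- function(object, ...) {
  df <- filter(object$measurements, .data$used)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_cm, y = .data$L_cm)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_line(
      data = mutate(df, L_fit = object$k * .data$delta_cm^(1 - object$D)),
      ggplot2::aes(y = .data$L_fit), colour = "steelblue") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(delta ~ "(cm)"), y = "L (cm)",
                  title = sprintf("D = %.3f (r² = %.3f)",
                                  object$D, object$r_squared))
}

#' Fractal dimension for every segment of a table
#'
#' Applies [fractal_mean()] to each segment with at least `min_locations`
#' points and returns a tidy per-segment table.
#'
#' @param segments Output of [build_paths()] (column `segment_id`).
#' @param config A [divider_config()] shared by all segments, or `NULL` to
#'   adapt the divider range to each path.
#' @param min_locations Minimum locations per segment.
#' @return Tibble with `segment_id` (plus `individual_id`/`treatment` when
#'   present), `D`, `k`, `r_squared`, `n_deltas_used`.
#' @export
fractal_dimension <- function(segments, config = NULL, min_locations = 5) {
  s <- filter_min_locations(segments, min_locations)
  if (nrow(s) == 0L) {
    return(tibble(segment_id = character(), D = numeric(), k = numeric(),
                  r_squared = numeric(), n_deltas_used = integer()))
  }
  idcols <- intersect(c("individual_id", "treatment"), names(s))
  split(s, s$segment_id) |>
    map(function(seg) {
      est <- fractal_mean(seg, config)
      out <- glance(est)[, c("D", "k", "r_squared", "n_deltas_used")]
      out$segment_id <- seg$segment_id[1]
      for (cc in idcols) out[[cc]] <- seg[[cc]][1]
      out[, c("segment_id", idcols, "D", "k", "r_squared", "n_deltas_used")]
    }) |>
    bind_rows()
}

#' Mean fractal dimension per individual
#'
#' When several paths are obtained for one individual, the per-segment
#' dimensions (segments meeting the minimum-location rule only) are averaged
#' with equal weight.
#'
#' @inheritParams fractal_dimension
#' @return Tibble with one row per individual: `individual_id`
#'   (and `treatment` if present), `D`, `n_segments`.
#' @export
fractal_per_individual <- function(segments, config = NULL,
                                   min_locations = 5) {
  s <- as_tibble(segments)
  if (!"individual_id" %in% names(s)) {
    s$individual_id <- "individual_1"
  }
  per_seg <- fractal_dimension(s, config, min_locations)
  if (nrow(per_seg) == 0L) abort("no eligible segment for any individual")
  grp <- intersect(c("individual_id", "treatment"), names(per_seg))
  per_seg |>
    group_by(across(all_of(grp))) |>
    summarise(D = mean(.data$D), n_segments = n(), .groups = "drop")
}
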
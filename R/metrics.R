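#' Step lengths of a path segment
#'
#' The step length is the Euclidean distance travelled per 1-s interval.
#' Each step is flagged as a relocation if it reaches the rest threshold
#' (default 0.1 cm, the calibrated noise margin); steps below it are resting
#' moments. A step exactly at the threshold counts as relocation.
#'
#' @param segment Tibble of one segment's points (`time_s`, `x_cm`, `y_cm`),
#'   >= 2 rows.
#' @param rest_threshold_cm Displacement threshold separating relocation
#'   from resting, cm.
#' @return Tibble with one row per interval: `time_s` (interval end),
#'   `step_cm`, `is_relocation`.
#' @export
step_lengths <- function(segment, rest_threshold_cm = 0.1) {
  s <- as_tibble(segment)
  if (nrow(s) < 2L) abort("`segment` needs at least 2 points")
  assert_number(rest_threshold_cm, "rest_threshold_cm", lower = 0)
  dx <- diff(s$x_cm)
  dy <- diff(s$y_cm)
  step <- sqrt(dx^2 + dy^2)
  tibble(time_s = s$time_s[-1], step_cm = step,
         is_relocation = step >= rest_threshold_cm)
}

#' Resting fraction of a step series
#'
#' Fraction of 1-s intervals whose displacement stays below the rest
#' threshold — the share of time the animal did not move.
#'
#' @param steps Output of [step_lengths()], or any tibble with `step_cm`.
#' @param rest_threshold_cm Threshold used to (re)classify the steps, cm.
#' @return One-row tibble: `resting_fraction`, `threshold_cm`, `n_steps`.
#' @export
resting_fraction <- function(steps, rest_threshold_cm = 0.1) {
  s <- as_tibble(steps)
  if (nrow(s) == 0L) abort("`steps` must contain at least one step")
  assert_number(rest_threshold_cm, "rest_threshold_cm", lower = 0)
  resting <- s$step_cm < rest_threshold_cm
  tibble(resting_fraction = mean(resting),
         threshold_cm = rest_threshold_cm,
         n_steps = nrow(s))
}

#' Turning angles of a path segment
#'
#' The turning angle is the signed deviation from straight-line locomotion
#' between successive displacement vectors, counterclockwise positive, in
#' `(-180, 180]` degrees. Angles are computed only between relocation steps
#' that are adjacent in time: a resting interval breaks the chain because
#' heading during rest is unobservable, and sub-threshold displacements are
#' positional noise.
#'
#' @inheritParams step_lengths
#' @return Tibble with `time_s` (the shared time point of the two steps) and
#'   `theta_deg`.
#' @export
turning_angles <- function(segment, rest_threshold_cm = 0.1) {
  s <- as_tibble(segment)
  if (nrow(s) < 3L) abort("`segment` needs at least 3 points")
  assert_number(rest_threshold_cm, "rest_threshold_cm", lower = 0)
  dx <- diff(s$x_cm)
  dy <- diff(s$y_cm)
  step <- sqrt(dx^2 + dy^2)
  reloc <- step >= rest_threshold_cm
  i <- seq_len(length(step) - 1L)
  ok <- reloc[i] & reloc[i + 1L]
  cross <- dx[i] * dy[i + 1L] - dy[i] * dx[i + 1L]
  dot <- dx[i] * dx[i + 1L] + dy[i] * dy[i + 1L]
  theta <- rad2deg(atan2(cross, dot))
  theta[theta <= -180] <- theta[theta <= -180] + 360
  tibble(time_s = s$time_s[i + 1L][ok], theta_deg = theta[ok])
}

#' Stops per distance travelled
#'
#' Number of move-to-rest transitions per metre of path, a measure of how
#' often locomotion is interrupted.
#'
#' @param steps Output of [step_lengths()].
#' @return A single number: stops per metre.
#' @export
stops_per_distance <- function(steps) {
  s <- as_tibble(steps)
  if (nrow(s) == 0L) abort("`steps` must contain at least one step")
  reloc_dist <- sum(s$step_cm[s$is_relocation])
  if (reloc_dist <= 0) abort("total relocation distance is zero")
  r <- s$is_relocation
  stops <- sum(r[-length(r)] & !r[-1])
  total_m <- sum(s$step_cm) / 100
  stops / total_m
}

#' Classify the step-length distribution as exponential or power-law
#'
#' Maximum-likelihood fits of a shifted exponential and a Pareto
#' distribution to the relocation step lengths above a common lower cutoff
#' `x_min`, compared by AIC. The verdict is the model ahead by more than
#' `delta_aic` (default 2, a conventional evidence bound); with fewer than
#' `min_n` eligible steps the verdict is `"inconclusive"` regardless.
#'
#' A heavy (power-law) tail — many short steps punctuated by rare long ones —
#' is the Levy-walk-like pattern; the exponential is the light-tailed
#' alternative with a characteristic scale.
#'
#' @param steps Output of [step_lengths()], or a numeric vector of step
#'   lengths in cm.
#' @param x_min Lower cutoff, cm; defaults to the rest threshold below which
#'   displacements are considered noise.
#' @param min_n Minimum number of eligible steps for a verdict.
#' @param delta_aic AIC margin required to call a winner.
#' @return A `step_dist_fit` object with `verdict`, the per-model `fits`
#'   tibble, and `delta_aic_observed`; see [tidy()] and [glance()].
#' @export
fit_step_distribution <- function(steps, x_min = 0.1, min_n = 50,
                                  delta_aic = 2) {
  assert_number(x_min, "x_min", lower = 1e-12)
  min_n <- assert_count(min_n, "min_n", lower = 2L)
  if (is.data.frame(steps)) {
    x <- steps$step_cm
    if ("is_relocation" %in% names(steps)) x <- x[steps$is_relocation]
  } else {
    x <- as.numeric(steps)
  }
  x <- x[!is.na(x) & x >= x_min]
  if (length(x) == 0L) abort("no steps at or above `x_min`")
  n <- length(x)
  xbar <- mean(x)
  if (xbar <= x_min) abort("steps are degenerate at `x_min`; cannot fit")

  rate_hat <- 1 / (xbar - x_min)
  ll_exp <- n * log(rate_hat) - rate_hat * sum(x - x_min)
  mu_hat <- 1 + n / sum(log(x / x_min))
  ll_pl <- n * log(mu_hat - 1) + (mu_hat - 1) * n * log(x_min) -
    mu_hat * sum(log(x))
  fits <- tibble(
    model = c("exponential", "powerlaw"),
    parameter = c("rate", "mu"),
    estimate = c(rate_hat, mu_hat),
    log_lik = c(ll_exp, ll_pl),
    aic = c(2 - 2 * ll_exp, 2 - 2 * ll_pl)
  )
  d_obs <- fits$aic[2] - fits$aic[1]  # positive favours exponential
  verdict <- if (n < min_n) {
    "inconclusive"
  } else if (d_obs > delta_aic) {
    "exponential"
  } else if (d_obs < -delta_aic) {
    "powerlaw"
  } else {
    "inconclusive"
  }
  structure(list(verdict = verdict, fits = fits,
                 delta_aic_observed = d_obs, n = n, x_min = x_min,
                 min_n = min_n, delta_aic = delta_aic, steps = x),
            class = "step_dist_fit")
}

#' @export
print.step_dist_fit <- function(x, ...) {
  cat(sprintf("Step-length distribution fit (n = %d, x_min = %g cm)\n",
              x$n, x$x_min))
  cat(sprintf("  verdict: %s (AIC difference %.2f)\n",
              x$verdict, x$delta_aic_observed))
  print(x$fits)
  invisible(x)
}

#' @describeIn fit_step_distribution Per-model fit table.
#' @param x A `step_dist_fit` object.
#' @param ... Unused.
#' @export
tidy.step_dist_fit <- function(x, ...) x$fits

#' @describeIn fit_step_distribution One-row verdict summary.
#' @export
glance.step_dist_fit <- function(x, ...) {
  tibble(verdict = x$verdict, delta_aic = x$delta_aic_observed,
         n_steps = x$n, x_min = x$x_min)
}

#' @describeIn fit_step_distribution Empirical tail plot with both fitted
#'   survival curves on log-log axes.
#' @param object A `step_dist_fit` object.
#' @export
autoplot.step_dist_fit <- function(object, ...) {
  x <- sort(object$steps)
  surv <- 1 - (seq_along(x) - 1) / length(x)
  rate <- object$fits$estimate[1]
  mu <- object$fits$estimate[2]
  grid <- exp(seq(log(min(x)), log(max(x)), length.out = 200))
  df <- tibble(step_cm = x, survival = surv)
  fit_df <- tibble(
    step_cm = rep(grid, 2),
    survival = c(exp(-rate * (grid - object$x_min)),
                 (grid / object$x_min)^(-(mu - 1))),
    model = rep(c("exponential", "powerlaw"), each = length(grid))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step_cm, y = .data$survival)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = fit_df,
                       ggplot2::aes(colour = .data$model)) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "step length (cm)", y = "P(step > x)",
                  colour = NULL,
                  title = sprintf("verdict: %s", object$verdict))
}
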
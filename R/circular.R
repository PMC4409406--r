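#' Circular summary statistics for turning angles
#'
#' Treats angles as points on the circle (180 deg is the same direction as
#' -180 deg). The circular mean is the direction of the resultant of the
#' unit vectors, the mean resultant length `R_bar` in `[0, 1]` measures
#' concentration, the circular SD is `sqrt(-2 log R_bar)` converted to
#' degrees, and the von Mises concentration `kappa` is obtained from
#' `R_bar` by the standard piecewise rational inversion of the Bessel-function
#' ratio. The arithmetic (linear) mean and SD are reported alongside, since
#' summary tables in this field sometimes print those instead.
#'
#' @param angles_deg Numeric vector of angles in degrees (>= 2 values),
#'   interpreted on `(-180, 180]`.
#' @return One-row tibble: `n`, `mean_deg`, `R_bar`, `sd_deg`, `kappa`,
#'   `mean_arith_deg`, `sd_arith_deg`. If `R_bar` is numerically zero the
#'   mean direction is undefined: `mean_deg` is `NA` with a warning.
#' @export
circular_summary <- function(angles_deg) {
  a <- as.numeric(angles_deg)
  a <- a[!is.na(a)]
  if (length(a) < 2L) abort("`angles_deg` needs at least 2 values")
  th <- deg2rad(wrap_deg(a))
  C <- mean(cos(th))
  S <- mean(sin(th))
  R <- sqrt(C^2 + S^2)
  if (R < 1e-12) {
    warn("mean resultant length is zero: circular mean undefined")
    mean_deg <- NA_real_
    R <- 0
  } else {
    mean_deg <- wrap_deg(rad2deg(atan2(S, C)))
  }
  sd_deg <- if (R > 0) rad2deg(sqrt(-2 * log(R))) else Inf
  tibble(n = length(a), mean_deg = mean_deg, R_bar = R, sd_deg = sd_deg,
         kappa = kappa_from_rbar(R),
         mean_arith_deg = mean(a), sd_arith_deg = sd(a))
}

# standard piecewise approximation to the inverse of A1(kappa) = R_bar
kappa_from_rbar <- function(R) {
  if (R < 0) R <- 0
  if (R >= 1) return(Inf)
  if (R < 0.53) {
    2 * R + R^3 + 5 * R^5 / 6
  } else if (R < 0.85) {
    -0.4 + 1.39 * R + 0.43 / (1 - R)
  } else {
    1 / (R^3 - 4 * R^2 + 3 * R)
  }
}

# deterministic sub-resolution jitter to break ties for circular ranks,
# without disturbing the caller's RNG stream
break_ties <- function(a) {
  if (!anyDuplicated(a)) return(a)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(285714L)
  a + runif(length(a), -5e-7, 5e-7)
}

#' Watson-Wheeler test for homogeneity of circular samples
#'
#' Nonparametric rank-based comparison of two or more groups of angles,
#' appropriate when concentrations differ between groups. Pooled angles are
#' converted to circular ranks and uniform scores `beta = 2 pi rank / N`;
#' the statistic is `W = 2 * sum_i (C_i^2 + S_i^2) / n_i` with `C_i`, `S_i`
#' the per-group sums of `cos beta`, `sin beta`, referred to a chi-squared
#' distribution with `2 (k - 1)` degrees of freedom. Exact ties are broken
#' by adding deterministic jitter far below measurement resolution
#' (< 1e-6 degrees).
#'
#' @param data Tibble in long format with one angle per row.
#' @param angle Name of the angle column (degrees); default `"theta_deg"`.
#' @param group Name of the grouping column; default `"group"`.
#' @return One-row tibble: `test`, `statistic`, `df`, `p_value`,
#'   `n_groups`, `n_total`. A warning is issued for groups smaller than 10,
#'   where the chi-squared approximation is unreliable.
#' @export
watson_wheeler <- function(data, angle = "theta_deg", group = "group") {
  d <- as_tibble(data)
  if (!angle %in% names(d)) abort(sprintf("column `%s` not found", angle))
  if (!group %in% names(d)) abort(sprintf("column `%s` not found", group))
  a <- as.numeric(d[[angle]])
  g <- as.factor(d[[group]])
  ok <- !is.na(a) & !is.na(g)
  a <- a[ok]; g <- droplevels(g[ok])
  k <- nlevels(g)
  if (k < 2L) abort("need at least 2 groups")
  n_i <- tabulate(g)
  if (any(n_i < 2L)) abort("every group needs at least 2 angles")
  if (any(n_i < 10L)) {
    warn("groups with fewer than 10 angles: chi-squared approximation is unreliable")
  }
  a <- break_ties(wrap_deg(a))
  N <- length(a)
  beta <- 2 * pi * rank(a, ties.method = "first") / N
  Cg <- tapply(cos(beta), g, sum)
  Sg <- tapply(sin(beta), g, sum)
  W <- 2 * sum((Cg^2 + Sg^2) / n_i)
  df <- 2 * (k - 1)
  tibble(test = "Watson-Wheeler", statistic = unname(W), df = df,
         p_value = pchisq(W, df, lower.tail = FALSE),
         n_groups = k, n_total = N)
}

#' Circular boxplot statistics
#'
#' Five-number-style summary on the circle: the circular median (the sample
#' angle minimising mean arc distance to all angles), hinges as the
#' quartiles of the signed arc deviations from the median, fences at
#' hinge +/- 1.5 times the circular IQR, and the angles beyond the fences
#' listed as outliers. Intended for reasonably concentrated unimodal
#' samples; a warning is issued when `R_bar < 0.2` and an error when the
#' sample has no usable concentration at all.
#'
#' @param angles_deg Numeric vector of at least 5 angles, degrees.
#' @return One-row tibble: `n`, `median_deg`, `hinge_lower_deg`,
#'   `hinge_upper_deg`, `iqr_deg`, `fence_lower_deg`, `fence_upper_deg`,
#'   `n_outliers` and a list-column `outliers_deg`.
#' @export
circular_boxplot_stats <- function(angles_deg) {
  a <- wrap_deg(as.numeric(angles_deg))
  a <- a[!is.na(a)]
  if (length(a) < 5L) abort("`angles_deg` needs at least 5 values")
  th <- deg2rad(a)
  R <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  if (R < 1e-8) abort("mean resultant length is ~0: circular median unstable")
  if (R < 0.2) {
    warn("low angular concentration (R_bar < 0.2): boxplot summary may be unstable")
  }
  cand <- sort(unique(a))
  cost <- vapply(cand, function(m) mean(abs(arc_deg(m, a))), numeric(1))
  med <- cand[which.min(cost)]  # ties: first in sorted order
  dev <- arc_deg(med, a)
  hinges <- quantile(dev, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- hinges[2] - hinges[1]
  fences <- c(hinges[1] - 1.5 * iqr, hinges[2] + 1.5 * iqr)
  out <- a[dev < fences[1] | dev > fences[2]]
  tibble(
    n = length(a), median_deg = med,
    hinge_lower_deg = wrap_deg(med + hinges[1]),
    hinge_upper_deg = wrap_deg(med + hinges[2]),
    iqr_deg = iqr,
    fence_lower_deg = wrap_deg(med + fences[1]),
    fence_upper_deg = wrap_deg(med + fences[2]),
    n_outliers = length(out),
    outliers_deg = list(out)
  )
}
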
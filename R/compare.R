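#' Compare treatments with the metric-appropriate test
#'
#' Dispatches each movement metric to its test:
#' \describe{
#'   \item{resting time}{Welch's t-test (2 groups) or one-way ANOVA (> 2).}
#'   \item{fractal dimension}{as resting time, after a `log(D - 1)`
#'     transform; estimates at or below 1 are clipped to `1 + 1e-6` with a
#'     warning.}
#'   \item{step length}{Wilcoxon rank-sum (2 groups) or Kruskal-Wallis
#'     (> 2), for the typically non-normal step data.}
#'   \item{turning angle}{[watson_wheeler()] on the pooled relocation
#'     angles.}
#' }
#' The unit of replication for the location tests is the individual; only
#' turning angles are pooled across individuals within a treatment.
#'
#' @param data For location tests, a per-individual metric table (e.g. from
#'   [individual_metrics()]); for `"turning_angle"`, a long table of pooled
#'   angles.
#' @param metric One of `"resting_time"`, `"step_length"`,
#'   `"fractal_dimension"`, `"turning_angle"`.
#' @param value Name of the value column; defaults to `resting_fraction`,
#'   `mean_step_cm`, `D` or `theta_deg` respectively.
#' @param group Name of the grouping column, default `"treatment"`.
#' @return One-row tibble: `metric`, `test`, `statistic`, `df`, `df_resid`,
#'   `p_value`, `transform`, `n_groups`.
#' @export
compare_treatments <- function(data,
                               metric = c("resting_time", "step_length",
                                          "fractal_dimension",
                                          "turning_angle"),
                               value = NULL, group = "treatment") {
  metric <- match.arg(metric)
  d <- as_tibble(data)
  if (is.null(value)) {
    value <- switch(metric, resting_time = "resting_fraction",
                    step_length = "mean_step_cm",
                    fractal_dimension = "D", turning_angle = "theta_deg")
  }
  if (!value %in% names(d)) abort(sprintf("column `%s` not found", value))
  if (!group %in% names(d)) abort(sprintf("column `%s` not found", group))

  if (metric == "turning_angle") {
    res <- watson_wheeler(d, angle = value, group = group)
    return(tibble(metric = metric, test = res$test,
                  statistic = res$statistic, df = res$df,
                  df_resid = NA_real_, p_value = res$p_value,
                  transform = "none", n_groups = res$n_groups))
  }

  x <- d[[value]]
  g <- droplevels(as.factor(d[[group]]))
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(g[ok])
  k <- nlevels(g)
  if (k < 2L) abort("need at least 2 groups")
  if (any(tabulate(g) < 3L)) {
    abort("every group needs at least 3 individuals for a location test")
  }

  transform <- "none"
  if (metric == "fractal_dimension") {
    n_clip <- sum(x <= 1)
    if (n_clip > 0) {
      warn(sprintf("%d fractal dimension value(s) <= 1 clipped to 1 + 1e-6 before log(D - 1)",
                   n_clip))
      x[x <= 1] <- 1 + 1e-6
    }
    x <- log(x - 1)
    transform <- "log(D-1)"
  }

  if (metric %in% c("resting_time", "fractal_dimension")) {
    if (k == 2L) {
      tt <- t.test(x ~ g)
      out <- tibble(test = "Welch t-test", statistic = unname(tt$statistic),
                    df = unname(tt$parameter), df_resid = NA_real_,
                    p_value = tt$p.value)
    } else {
      s <- summary(aov(x ~ g))[[1]]
      out <- tibble(test = "one-way ANOVA", statistic = s$`F value`[1],
                    df = s$Df[1], df_resid = s$Df[2],
                    p_value = s$`Pr(>F)`[1])
    }
  } else {  # step_length
    if (k == 2L) {
      wt <- wilcox.test(x ~ g)
      out <- tibble(test = "Wilcoxon rank-sum",
                    statistic = unname(wt$statistic), df = NA_real_,
                    df_resid = NA_real_, p_value = wt$p.value)
    } else {
      kt <- kruskal.test(x, g)
      out <- tibble(test = "Kruskal-Wallis",
                    statistic = unname(kt$statistic),
                    df = unname(kt$parameter), df_resid = NA_real_,
                    p_value = kt$p.value)
    }
  }
  tibble(metric = metric, test = out$test, statistic = out$statistic,
         df = out$df, df_resid = out$df_resid, p_value = out$p_value,
         transform = transform, n_groups = k)
}

#' Per-segment movement metrics
#'
#' Computes the full metric set for every segment that meets the
#' minimum-location rule: step statistics, resting fraction, stop rate and
#' (optionally) the divider-method fractal dimension.
#'
#' @param segments Output of [build_paths()].
#' @param rest_threshold_cm Rest threshold, cm.
#' @param divider A [divider_config()], `NULL` to adapt the divider range to
#'   each path, or `FALSE` to skip fractal estimation.
#' @param min_locations Minimum locations per segment.
#' @return Per-segment tibble of metrics.
#' @export
segment_metrics <- function(segments, rest_threshold_cm = 0.1,
                            divider = NULL, min_locations = 5) {
  s <- filter_min_locations(segments, min_locations)
  idcols <- intersect(c("individual_id", "treatment"), names(s))
  if (nrow(s) == 0L) {
    return(tibble(segment_id = character()))
  }
  rows <- split(s, s$segment_id) |>
    map(function(seg) {
      st <- step_lengths(seg, rest_threshold_cm)
      reloc <- st$step_cm[st$is_relocation]
      out <- tibble(
        segment_id = seg$segment_id[1],
        n_points = nrow(seg),
        duration_s = nrow(seg) - 1,
        n_steps = nrow(st),
        n_relocations = sum(st$is_relocation),
        total_distance_cm = sum(st$step_cm),
        mean_step_cm = if (length(reloc)) mean(reloc) else NA_real_,
        resting_fraction = mean(!st$is_relocation),
        n_stops = sum(st$is_relocation[-nrow(st)] &
                        !st$is_relocation[-1]),
        stops_per_m = if (sum(reloc) > 0) stops_per_distance(st) else NA_real_
      )
      for (cc in idcols) out[[cc]] <- seg[[cc]][1]
      out
    }) |>
    bind_rows()
  if (!isFALSE(divider)) {
    fd <- fractal_dimension(s, config = divider, min_locations = min_locations)
    rows <- left_join(rows,
                      fd[, c("segment_id", "D", "r_squared")],
                      by = "segment_id")
  }
  rows[, c(intersect(c("individual_id", "treatment"), names(rows)),
           setdiff(names(rows), c("individual_id", "treatment")))]
}

#' Per-individual movement metrics
#'
#' Aggregates per-segment metrics to one row per individual: steps and
#' resting intervals are pooled across the individual's segments (the
#' resting fraction is the pooled fraction of intervals, the mean step the
#' pooled mean over relocation steps), while the fractal dimension is the
#' unweighted mean of the per-segment estimates.
#'
#' @param seg_metrics Output of [segment_metrics()].
#' @return Per-individual tibble.
#' @export
individual_metrics <- function(seg_metrics) {
  m <- as_tibble(seg_metrics)
  if (!"individual_id" %in% names(m)) m$individual_id <- "individual_1"
  grp <- intersect(c("individual_id", "treatment"), names(m))
  m |>
    group_by(across(all_of(grp))) |>
    summarise(
      # interval-weighted pooling first: summarise() evaluates sequentially,
      # so the totals that reuse these column names must come last
      n_segments = n(),
      pooled_resting = sum(.data$resting_fraction * .data$n_steps) /
        sum(.data$n_steps),
      pooled_step = sum(.data$mean_step_cm * .data$n_relocations,
                        na.rm = TRUE) /
        sum(.data$n_relocations[!is.na(.data$mean_step_cm)]),
      stops_per_m = if (sum(.data$total_distance_cm) > 0)
        sum(.data$n_stops) / (sum(.data$total_distance_cm) / 100)
      else NA_real_,
      D = if ("D" %in% names(m)) mean(.data$D[!is.na(.data$D)]) else NA_real_,
      n_steps = sum(.data$n_steps),
      total_distance_cm = sum(.data$total_distance_cm),
      .groups = "drop"
    ) |>
    dplyr::rename(resting_fraction = "pooled_resting",
                  mean_step_cm = "pooled_step") |>
    select(all_of(c(grp, "n_segments", "n_steps", "resting_fraction",
                    "mean_step_cm", "total_distance_cm", "stops_per_m",
                    "D")))
}

#' Treatment-level summary table
#'
#' Mirrors the standard bookkeeping-plus-metrics summary of a tracking
#' study: per treatment, the retained share of recorded time points, the
#' number and duration of paths, and mean +/- SD (over individuals) of
#' resting time, step length and fractal dimension, plus circular and
#' arithmetic summaries of the pooled turning angles.
#'
#' @param segments Output of [build_paths()] with `treatment` and
#'   `individual_id` columns.
#' @param recording_points_per_individual Recorded time points per
#'   individual (default 3600, an hour at 1 Hz), used for the availability
#'   percentage.
#' @inheritParams segment_metrics
#' @return One row per treatment.
#' @export
build_summary_table <- function(segments, rest_threshold_cm = 0.1,
                                divider = NULL, min_locations = 5,
                                recording_points_per_individual = 3600) {
  s <- as_tibble(segments)
  if (!all(c("treatment", "individual_id") %in% names(s))) {
    abort("`segments` needs `treatment` and `individual_id` columns")
  }
  if (nrow(s) == 0L) abort("no segments to summarise")
  sm <- segment_metrics(s, rest_threshold_cm, divider, min_locations)
  im <- individual_metrics(sm)
  sf <- filter_min_locations(s, min_locations)

  split(im, im$treatment) |>
    map(function(g) {
      tr <- g$treatment[1]
      seg_tr <- sf[sf$treatment == tr, , drop = FALSE]
      sizes <- as.integer(table(seg_tr$segment_id))
      ang <- split(seg_tr, seg_tr$segment_id) |>
        map(turning_angles, rest_threshold_cm = rest_threshold_cm) |>
        bind_rows()
      circ <- if (nrow(ang) >= 2L) circular_summary(ang$theta_deg) else NULL
      total_pts <- recording_points_per_individual *
        n_distinct(s$individual_id[s$treatment == tr])
      tibble(
        treatment = tr,
        n_individuals = nrow(g),
        available_points_pct = 100 * nrow(seg_tr) / total_pts,
        n_paths = length(sizes),
        duration_mean_s = mean(sizes - 1),
        duration_sd_s = if (length(sizes) > 1) sd(sizes - 1) else NA_real_,
        resting_pct_mean = 100 * mean(g$resting_fraction),
        resting_pct_sd = if (nrow(g) > 1) 100 * sd(g$resting_fraction)
          else NA_real_,
        step_cm_mean = mean(g$mean_step_cm, na.rm = TRUE),
        step_cm_sd = if (nrow(g) > 1) sd(g$mean_step_cm) else NA_real_,
        turn_mean_deg = if (!is.null(circ)) circ$mean_deg else NA_real_,
        turn_sd_circ_deg = if (!is.null(circ)) circ$sd_deg else NA_real_,
        turn_sd_arith_deg = if (!is.null(circ)) circ$sd_arith_deg
          else NA_real_,
        fractal_d_mean = mean(g$D, na.rm = TRUE),
        fractal_d_sd = if (nrow(g) > 1) sd(g$D) else NA_real_
      )
    }) |>
    bind_rows()
}

#' Pool turning angles per treatment
#'
#' Long-format table of all relocation turning angles of each treatment's
#' segments, the input to [watson_wheeler()] and the circular summaries.
#'
#' @inheritParams segment_metrics
#' @return Tibble with `treatment`, `individual_id`, `segment_id`,
#'   `time_s`, `theta_deg`.
#' @export
pooled_turning_angles <- function(segments, rest_threshold_cm = 0.1,
                                  min_locations = 5) {
  s <- filter_min_locations(segments, min_locations)
  idcols <- intersect(c("individual_id", "treatment"), names(s))
  if (nrow(s) == 0L) {
    return(tibble(segment_id = character(), time_s = numeric(),
                  theta_deg = numeric()))
  }
  split(s, s$segment_id) |>
    map(function(seg) {
      if (nrow(seg) < 3L) return(NULL)
      a <- turning_angles(seg, rest_threshold_cm)
      if (nrow(a) == 0L) return(NULL)
      a$segment_id <- seg$segment_id[1]
      for (cc in idcols) a[[cc]] <- seg[[cc]][1]
      a
    }) |>
    bind_rows()
}
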
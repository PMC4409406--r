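#' Arena geometry and sampling configuration
#'
#' @param width_cm,height_cm Arena dimensions, cm (default the 1 m2 arena).
#' @param margin_cm Width of the wall margin excluded from analysis to avoid
#'   fence (wall-following) behaviour, cm.
#' @param frame_rate_hz Sampling rate; one position per second by default.
#' @return An `arena_config` object.
#' @export
arena_config <- function(width_cm = 100, height_cm = 100, margin_cm = 10,
                         frame_rate_hz = 1) {
  assert_number(width_cm, "width_cm", lower = 1e-9)
  assert_number(height_cm, "height_cm", lower = 1e-9)
  assert_number(margin_cm, "margin_cm", lower = 0)
  assert_number(frame_rate_hz, "frame_rate_hz", lower = 1e-9)
  if (margin_cm >= min(width_cm, height_cm) / 2) {
    abort("`margin_cm` must be smaller than half the smaller arena dimension")
  }
  structure(list(width_cm = width_cm, height_cm = height_cm,
                 margin_cm = margin_cm, frame_rate_hz = frame_rate_hz),
            class = "arena_config")
}

#' Segment a detection series into analysis-ready path segments
#'
#' Drops time points that are missing (`present == FALSE`) or that lie within
#' the wall margin (distance to the nearest wall <= `margin_cm`; the margin
#' boundary itself is excluded), then cuts every maximal run of consecutive
#' retained points (unit time gaps) into one path segment. Margin excursions
#' and detection gaps both split segments; nothing is interpolated across
#' unobserved intervals. If `individual_id` / `treatment` columns are present,
#' segmentation is carried out within each individual and the labels are kept.
#'
#' @param detections Tibble with `time_s`, `x_cm`, `y_cm`, optionally
#'   `present`, `individual_id`, `treatment`.
#' @param arena An [arena_config()].
#' @return Tibble of retained points with a `segment_id` column.
#' @export
build_paths <- function(detections, arena = arena_config()) {
  stopifnot(inherits(arena, "arena_config"))
  d <- as_tibble(detections)
  empty <- tibble(segment_id = character(), time_s = numeric(),
                  x_cm = numeric(), y_cm = numeric())
  if (nrow(d) == 0L) return(empty)
  if (!all(c("time_s", "x_cm", "y_cm") %in% names(d))) {
    abort("`detections` needs columns time_s, x_cm, y_cm")
  }
  if (!"present" %in% names(d)) d$present <- TRUE
  idcols <- intersect(c("individual_id", "treatment"), names(d))

  m <- arena$margin_cm
  keep <- d$present & !is.na(d$x_cm) & !is.na(d$y_cm) &
    d$x_cm > m & d$x_cm < arena$width_cm - m &
    d$y_cm > m & d$y_cm < arena$height_cm - m
  d <- d[keep, , drop = FALSE]
  if (nrow(d) == 0L) return(empty)

  dt <- 1 / arena$frame_rate_hz
  key <- if ("individual_id" %in% idcols) d$individual_id else rep("", nrow(d))
  ord <- order(key, d$time_s)
  d <- d[ord, , drop = FALSE]
  key <- key[ord]
  new_run <- c(TRUE, diff(d$time_s) != dt | key[-1] != key[-length(key)])
  run <- cumsum(new_run)
  d$segment_id <- if ("individual_id" %in% idcols) {
    sprintf("%s_s%03d", d$individual_id, as.integer(ave(run, key, FUN = function(r) match(r, unique(r)))))
  } else {
    sprintf("s%03d", run)
  }
  d[, c("segment_id", idcols, "time_s", "x_cm", "y_cm")]
}

#' Drop path segments with too few locations
#'
#' Segments shorter than `min_locations` points are excluded before any
#' metric is computed, so that step, turn, resting and fractal statistics all
#' describe the same set of paths.
#'
#' @param segments Output of [build_paths()].
#' @param min_locations Minimum number of locations per segment (>= 2);
#'   default 5.
#' @return The surviving rows of `segments`.
#' @export
filter_min_locations <- function(segments, min_locations = 5) {
  min_locations <- assert_count(min_locations, "min_locations", lower = 2L)
  s <- as_tibble(segments)
  if (nrow(s) == 0L) return(s)
  counts <- table(s$segment_id)
  keep <- names(counts)[counts >= min_locations]
  s[s$segment_id %in% keep, , drop = FALSE]
}

#' Bookkeeping summary of retained paths
#'
#' Reports how much of the recording survived the margin, gap and
#' minimum-length rules: the number of segments, mean and SD of segment
#' duration (a segment of n points lasts `n - 1` seconds), and the retained
#' share of all recorded time points.
#'
#' @param segments Output of [build_paths()] (optionally filtered).
#' @param total_recording_points Total number of recorded time points the
#'   segments were extracted from.
#' @return A one-row tibble: `n_paths`, `mean_duration_s`, `sd_duration_s`,
#'   `available_points_pct`.
#' @export
summarize_paths <- function(segments, total_recording_points) {
  total_recording_points <- assert_count(total_recording_points,
                                         "total_recording_points", lower = 1L)
  s <- as_tibble(segments)
  if (nrow(s) > total_recording_points) {
    abort("`total_recording_points` is smaller than the number of retained points")
  }
  if (nrow(s) == 0L) {
    return(tibble(n_paths = 0L, mean_duration_s = NA_real_,
                  sd_duration_s = NA_real_, available_points_pct = 0))
  }
  sizes <- as.integer(table(s$segment_id))
  dur <- (sizes - 1)
  tibble(
    n_paths = length(sizes),
    mean_duration_s = mean(dur),
    sd_duration_s = if (length(dur) > 1L) sd(dur) else NA_real_,
    available_points_pct = 100 * nrow(s) / total_recording_points
  )
}
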
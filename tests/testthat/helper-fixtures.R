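# shared fixtures and independent oracles, built in code at test time

# huge arena centred start: no wall reflection, so recovered statistics are
# untouched by boundary handling
open_arena <- function() arena_config(1e6, 1e6, margin_cm = 10)

crw_open <- function(n_steps, ..., jitter_sd_cm = 0) {
  crw_params(n_steps = n_steps, ..., jitter_sd_cm = jitter_sd_cm,
             start_xy_cm = c(5e5, 5e5), arena = open_arena())
}

# per-individual resting fraction and mean relocation step, computed through
# the package's metric primitives (no margin filtering)
quick_individual_metrics <- function(traj, threshold = 0.1) {
  split(traj, traj$individual_id) |>
    lapply(function(d) {
      st <- step_lengths(d, threshold)
      tibble::tibble(
        individual_id = d$individual_id[1],
        treatment = d$treatment[1],
        resting_fraction = resting_fraction(st, threshold)$resting_fraction,
        mean_step_cm = mean(st$step_cm[st$is_relocation]))
    }) |>
    dplyr::bind_rows()
}

# brute-force enumeration oracle for the margin + gap + minimum-length rules:
# plain loops, independent of build_paths()'s vectorised run logic
oracle_segment_times <- function(det, arena, min_locations) {
  keep <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    keep[i] <- isTRUE(det$present[i]) &&
      !is.na(det$x_cm[i]) && !is.na(det$y_cm[i]) &&
      det$x_cm[i] > arena$margin_cm &&
      det$x_cm[i] < arena$width_cm - arena$margin_cm &&
      det$y_cm[i] > arena$margin_cm &&
      det$y_cm[i] < arena$height_cm - arena$margin_cm
  }
  segs <- list()
  cur <- integer(0)
  for (i in seq_len(nrow(det))) {
    if (keep[i]) {
      if (length(cur) > 0 && det$time_s[i] - det$time_s[cur[length(cur)]] != 1) {
        segs[[length(segs) + 1]] <- cur
        cur <- integer(0)
      }
      cur <- c(cur, i)
    } else if (length(cur) > 0) {
      segs[[length(segs) + 1]] <- cur
      cur <- integer(0)
    }
  }
  if (length(cur) > 0) segs[[length(segs) + 1]] <- cur
  segs <- Filter(function(s) length(s) >= min_locations, segs)
  lapply(segs, function(s) as.numeric(det$time_s[s]))
}

random_detection_series <- function(n = 120) {
  tibble::tibble(
    time_s = 0:(n - 1),
    x_cm = runif(n, 0, 100),
    y_cm = runif(n, 0, 100),
    present = runif(n) > 0.2
  )
}

# rigid rotation of a segment about the origin
rotate_segment <- function(seg, angle_deg) {
  th <- angle_deg * pi / 180
  tibble::tibble(
    time_s = seg$time_s,
    x_cm = seg$x_cm * cos(th) - seg$y_cm * sin(th),
    y_cm = seg$x_cm * sin(th) + seg$y_cm * cos(th))
}
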
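#' Pipeline configuration
#'
#' Validated bundle of every setting the end-to-end pipeline needs. Exactly
#' one of `input_csv` (trajectory/detection table) or `frames_dir` (rendered
#' frame directory with sidecar) must be given. Unknown settings are
#' rejected.
#'
#' @param input_csv Path to a trajectory or detection CSV.
#' @param frames_dir Path to a frame directory written by [write_frames()].
#' @param out_dir Output directory for stage CSVs and the manifest.
#' @param seed Integer seed recorded in the manifest and used for any
#'   stochastic stage.
#' @param arena An [arena_config()].
#' @param detect A [detect_config()].
#' @param rest_threshold_cm Rest threshold, cm.
#' @param divider A [divider_config()] or `NULL` for per-path ranges.
#' @param min_locations Minimum locations per segment.
#' @param recording_points_per_individual Recorded points per individual for
#'   the availability bookkeeping.
#' @param ... Unknown settings; supplying any is an error.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(input_csv = NULL, frames_dir = NULL,
                            out_dir = tempfile("macromove_run_"),
                            seed = 1L,
                            arena = arena_config(),
                            detect = detect_config(),
                            rest_threshold_cm = 0.1,
                            divider = NULL,
                            min_locations = 5,
                            recording_points_per_individual = 3600,
                            ...) {
  extra <- list(...)
  if (length(extra) > 0L) {
    abort(sprintf("unknown pipeline setting(s): %s",
                  paste(names(extra), collapse = ", ")))
  }
  if (is.null(input_csv) == is.null(frames_dir)) {
    abort("exactly one of `input_csv` or `frames_dir` must be given")
  }
  seed <- assert_count(seed, "seed", lower = 0L)
  stopifnot(inherits(arena, "arena_config"), inherits(detect, "detect_config"))
  assert_number(rest_threshold_cm, "rest_threshold_cm", lower = 0)
  if (!is.null(divider) && !isFALSE(divider)) {
    stopifnot(inherits(divider, "divider_config"))
  }
  min_locations <- assert_count(min_locations, "min_locations", lower = 2L)
  recording_points_per_individual <-
    assert_count(recording_points_per_individual,
                 "recording_points_per_individual", lower = 1L)
  structure(list(input_csv = input_csv, frames_dir = frames_dir,
                 out_dir = out_dir, seed = seed, arena = arena,
                 detect = detect, rest_threshold_cm = rest_threshold_cm,
                 divider = divider, min_locations = min_locations,
                 recording_points_per_individual =
                   recording_points_per_individual),
            class = "pipeline_config")
}

#' Run the full movement-analysis pipeline
#'
#' Executes the stages in order — track (if starting from frames), path
#' segmentation, per-segment and per-individual metrics, fractal
#' estimation, pooled turning angles, treatment summary and (when at least
#' two treatments with three or more individuals each are present) the
#' treatment comparisons — writing each stage's CSV into `out_dir`
#' together with a `manifest.txt` recording the configuration hash, seed
#' and stage counts. Re-running with the same configuration and inputs
#' reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a run report: list with `outputs` (named file paths),
#'   `counts` and `config_hash`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  if (!is.null(config$frames_dir)) {
    frames <- read_frames(config$frames_dir)
    det <- track_sequence(frames, config$detect)
    say("track: %d frames, %d detections present", length(frames$frames),
        sum(det$present))
    outputs["detections"] <- file.path(config$out_dir, "detections.csv")
    write_detections_csv(det, outputs["detections"])
  } else {
    if (!file.exists(config$input_csv)) {
      abort(sprintf("stage input: file `%s` not found", config$input_csv))
    }
    det <- read_detections_csv(config$input_csv)
    say("input: %d rows read", nrow(det))
  }

  segments <- build_paths(det, config$arena)
  n_dropped <- nrow(det) - nrow(segments)
  segments_kept <- filter_min_locations(segments, config$min_locations)
  say("paths: %d points retained (%d dropped by margin/gap), %d segments, %d after >=%d-location rule",
      nrow(segments), n_dropped, n_distinct(segments$segment_id),
      n_distinct(segments_kept$segment_id), config$min_locations)
  if (nrow(segments_kept) == 0L) {
    abort("stage paths: no segment survives the margin, gap and minimum-location rules")
  }
  outputs["segments"] <- file.path(config$out_dir, "segments.csv")
  write_trajectory_csv(segments_kept, outputs["segments"])

  sm <- segment_metrics(segments_kept, config$rest_threshold_cm,
                        config$divider, config$min_locations)
  say("metrics: %d segments", nrow(sm))
  outputs["segment_metrics"] <- file.path(config$out_dir,
                                          "segment_metrics.csv")
  readr::write_csv(sm, outputs["segment_metrics"])

  im <- individual_metrics(sm)
  outputs["individual_metrics"] <- file.path(config$out_dir,
                                             "individual_metrics.csv")
  readr::write_csv(im, outputs["individual_metrics"])

  ang <- pooled_turning_angles(segments_kept, config$rest_threshold_cm,
                               config$min_locations)
  say("angles: %d pooled turning angles", nrow(ang))
  outputs["angles"] <- file.path(config$out_dir, "angles.csv")
  readr::write_csv(ang, outputs["angles"])

  has_treat <- "treatment" %in% names(segments_kept) &&
    n_distinct(segments_kept$treatment) >= 2L
  if (has_treat) {
    st <- build_summary_table(segments_kept, config$rest_threshold_cm,
                              config$divider, config$min_locations,
                              config$recording_points_per_individual)
    outputs["summary_table"] <- file.path(config$out_dir,
                                          "summary_table.csv")
    readr::write_csv(st, outputs["summary_table"])
    enough <- all(table(im$treatment) >= 3L)
    if (enough) {
      cmp <- bind_rows(
        compare_treatments(im, "resting_time"),
        compare_treatments(im, "step_length"),
        if (!isFALSE(config$divider) && "D" %in% names(im) &&
            !all(is.na(im$D)))
          compare_treatments(im, "fractal_dimension"),
        if (nrow(ang) >= 4L)
          compare_treatments(ang, "turning_angle", group = "treatment")
      )
      outputs["comparisons"] <- file.path(config$out_dir, "comparisons.csv")
      readr::write_csv(cmp, outputs["comparisons"])
      say("compare: %d tests run", nrow(cmp))
    } else {
      say("compare: skipped (fewer than 3 individuals in a treatment)")
    }
  }

  cfg_hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  manifest <- c(
    sprintf("config_hash=%s", cfg_hash),
    sprintf("seed=%d", config$seed),
    log_lines,
    sprintf("output=%s", basename(outputs))
  )
  writeLines(manifest, file.path(config$out_dir, "manifest.txt"))
  outputs["manifest"] <- file.path(config$out_dir, "manifest.txt")

  invisible(list(outputs = outputs, counts = log_lines,
                 config_hash = cfg_hash))
}

#' Write a packaged synthetic dataset for tests and examples
#'
#' Generates the reference paths (straight line, level-5 Koch polyline,
#' Brownian motion), a correlated-random-walk cohort across two
#' density-like scenarios, and a small rendered frame set, and writes them
#' under `dir` with a manifest listing every artifact.
#'
#' @param dir Target directory.
#' @param seed Integer master seed.
#' @return Invisibly, the manifest tibble (artifact, path).
#' @export
make_fixtures <- function(dir = tempfile("macromove_fixtures_"), seed = 1L) {
  seed <- assert_count(seed, "seed", lower = 0L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(seed, 4)

  paths <- c(
    straight = file.path(dir, "straight.csv"),
    koch = file.path(dir, "koch_level5.csv"),
    brownian = file.path(dir, "brownian.csv"),
    cohort = file.path(dir, "crw_cohort.csv"),
    frames = file.path(dir, "frames")
  )
  write_trajectory_csv(generate_reference_path("straight", 100, 101),
                       paths["straight"])
  write_trajectory_csv(generate_reference_path("koch", 100, level = 5),
                       paths["koch"])
  write_trajectory_csv(generate_brownian(2000, 0.1, seed = seeds[1],
                                         start_xy_cm = c(50, 50)),
                       paths["brownian"])

  low <- crw_params(n_steps = 600, p_move_to_rest = 0.1,
                    p_rest_to_move = 0.25)
  high <- crw_params(n_steps = 600, p_move_to_rest = 0.25,
                     p_rest_to_move = 0.1)
  cohort <- generate_density_experiment(
    list(low_density = low, high_density = high),
    n_individuals = 5, seed = seeds[2])
  write_trajectory_csv(
    cohort[, c("time_s", "x_cm", "y_cm", "individual_id", "treatment")],
    paths["cohort"])

  small_arena <- arena_config(40, 40, margin_cm = 5)
  walker <- crw_params(n_steps = 30, p_move_to_rest = 0.05,
                       p_rest_to_move = 0.5, start_xy_cm = c(20, 20),
                       arena = small_arena)
  tr <- generate_crw(walker, seed = seeds[3])
  fs <- render_frames(tr, scene_config(arena = small_arena, px_per_cm = 4,
                                       occlusion_prob = 0.1),
                      seed = seeds[4])
  write_frames(fs, paths["frames"])

  manifest <- tibble(artifact = names(paths), path = unname(paths))
  readr::write_csv(manifest, file.path(dir, "fixture_manifest.csv"))
  invisible(manifest)
}
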
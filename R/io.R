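#' Read and write trajectory / detection tables as CSV
#'
#' Plain comma-separated files with a header row, point decimal and UTF-8
#' encoding. Trajectory files carry `time_s`, `x_cm`, `y_cm` and optionally
#' `individual_id`, `treatment`; detection files additionally `present` and
#' `blob_area_px`; segment files a `segment_id` column.
#'
#' @param data Tibble to write.
#' @param path File path.
#' @return `read_*` return tibbles; `write_*` the path, invisibly.
#' @export
write_trajectory_csv <- function(data, path) {
  readr::write_csv(as_tibble(data), path)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time_s", "x_cm", "y_cm")
  if (!all(need %in% names(d))) {
    abort(sprintf("trajectory CSV must have columns %s",
                  paste(need, collapse = ", ")))
  }
  d
}

#' @rdname write_trajectory_csv
#' @export
write_detections_csv <- function(data, path) {
  readr::write_csv(as_tibble(data), path)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_detections_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"present" %in% names(d)) d$present <- !is.na(d$x_cm)
  d
}
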
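#' Detection configuration
#'
#' @param k_sd Threshold is background mean plus `k_sd` background SDs.
#' @param min_area_px Minimum connected-component area, pixels; rejects hot
#'   pixels at the few-pixels-per-marker scale.
#' @return A `detect_config` object.
#' @export
detect_config <- function(k_sd = 5, min_area_px = 4) {
  assert_number(k_sd, "k_sd", lower = 0)
  min_area_px <- assert_count(min_area_px, "min_area_px", lower = 1L)
  structure(list(k_sd = k_sd, min_area_px = min_area_px),
            class = "detect_config")
}

#' Detect the marker blob in a single frame
#'
#' Background statistics are estimated per frame from the pixel population
#' excluding the top 1% intensities (self-calibrating against lamp drift);
#' pixels above `mean + k_sd * SD` form the candidate mask, the largest
#' connected component of at least `min_area_px` pixels is taken as the
#' marker, and its position is the intensity-weighted centre of gravity of
#' the member pixels, converted to arena cm (origin bottom-left, y up).
#'
#' @param frame Integer/numeric matrix with a `px_per_cm` attribute.
#' @param cfg A [detect_config()].
#' @return One-row tibble: `x_cm`, `y_cm`, `present`, `blob_area_px`.
#' @export
detect_marker <- function(frame, cfg = detect_config()) {
  stopifnot(inherits(cfg, "detect_config"))
  ppc <- attr(frame, "px_per_cm")
  if (is.null(ppc)) abort("`frame` is missing its px_per_cm scale attribute")
  v <- as.numeric(frame)
  q99 <- quantile(v, 0.99, names = FALSE)
  bg <- v[v <= q99]
  thr <- mean(bg) + cfg$k_sd * sd(bg)
  mask <- frame > thr
  none <- tibble(x_cm = NA_real_, y_cm = NA_real_, present = FALSE,
                 blob_area_px = 0L)
  if (!any(mask)) return(none)
  lab <- EBImage::imageData(
    EBImage::bwlabel(matrix(as.numeric(mask), nrow(frame))))
  areas <- tabulate(lab[lab > 0])
  best <- which.max(areas)
  if (areas[best] < cfg$min_area_px) return(none)
  idx <- which(lab == best, arr.ind = TRUE)
  wts <- as.numeric(frame[lab == best])
  nr <- nrow(frame)
  x_px <- sum((idx[, 2] - 0.5) * wts) / sum(wts)
  y_px <- sum((nr - idx[, 1] + 0.5) * wts) / sum(wts)
  tibble(x_cm = x_px / ppc, y_cm = y_px / ppc, present = TRUE,
         blob_area_px = areas[best])
}

#' Track a whole frame sequence
#'
#' Applies [detect_marker()] to each frame of a time-ordered, uniformly
#' 1-s-spaced sequence. Occluded or undetectable frames yield
#' `present = FALSE` rows; nothing is interpolated.
#'
#' @param frames A `frame_sequence` from [render_frames()] or
#'   [read_frames()].
#' @param cfg A [detect_config()].
#' @return Tibble of detections: `time_s`, `x_cm`, `y_cm`, `present`,
#'   `blob_area_px`.
#' @export
track_sequence <- function(frames, cfg = detect_config()) {
  stopifnot(inherits(frames, "frame_sequence"))
  n <- length(frames$frames)
  if (n == 0L) {
    return(tibble(time_s = numeric(), x_cm = numeric(), y_cm = numeric(),
                  present = logical(), blob_area_px = integer()))
  }
  dt <- 1 / frames$arena$frame_rate_hz
  if (n > 1L && any(abs(diff(frames$time_s) - dt) > 1e-9)) {
    abort("frame timestamps are not uniformly spaced")
  }
  det <- map(frames$frames, detect_marker, cfg = cfg) |> bind_rows()
  det$time_s <- frames$time_s
  det[, c("time_s", "x_cm", "y_cm", "present", "blob_area_px")]
}

#' Calibrate the tracking noise floor from a stationary marker
#'
#' Given detections of a marker known not to move (e.g. paper chips placed
#' in the arena and recorded for several minutes), reports the largest
#' absolute frame-to-frame displacement per axis and a recommended resting
#' threshold: twice the largest per-axis error, but never below 0.1 cm —
#' the margin that also absorbs small in-place body movements (breathing)
#' of a resting animal.
#'
#' @param detections Tibble from [track_sequence()]; at least 60 present
#'   detections are required.
#' @return One-row tibble: `max_abs_dx_cm`, `max_abs_dy_cm`,
#'   `recommended_rest_threshold_cm`.
#' @export
estimate_noise_floor <- function(detections) {
  d <- as_tibble(detections)
  d <- d[d$present, , drop = FALSE]
  if (nrow(d) < 60L) {
    abort("need at least 60 present detections of the stationary marker")
  }
  mdx <- max(abs(diff(d$x_cm)))
  mdy <- max(abs(diff(d$y_cm)))
  tibble(max_abs_dx_cm = mdx, max_abs_dy_cm = mdy,
         recommended_rest_threshold_cm = max(0.1, 2 * max(mdx, mdy)))
}
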
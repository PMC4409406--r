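#' Scene configuration for synthetic frame rendering
#'
#' Describes the imaging model used to render a trajectory into 8-bit
#' grayscale frames: a 2-D Gaussian marker blob on Gaussian background
#' noise, with optional per-frame marker invisibility emulating fluorescence
#' dropout at unfavourable marker angles.
#'
#' @param arena An [arena_config()].
#' @param px_per_cm Spatial resolution of the frames.
#' @param blob_sigma_px Point-spread width of the marker blob, pixels.
#' @param blob_peak Peak intensity added by the blob (8-bit scale, 0-255);
#'   must exceed `background_mean`.
#' @param background_mean,background_sd Background intensity model.
#' @param occlusion_prob Per-frame probability that the marker is invisible.
#' @return A `scene_config` object.
#' @export
scene_config <- function(arena = arena_config(), px_per_cm = 4,
                         blob_sigma_px = 2, blob_peak = 180,
                         background_mean = 30, background_sd = 4,
                         occlusion_prob = 0) {
  stopifnot(inherits(arena, "arena_config"))
  assert_number(px_per_cm, "px_per_cm", lower = 1e-9)
  assert_number(blob_sigma_px, "blob_sigma_px", lower = 1e-9)
  assert_number(blob_peak, "blob_peak", 0, 255)
  assert_number(background_mean, "background_mean", 0, 255)
  assert_number(background_sd, "background_sd", lower = 0)
  assert_number(occlusion_prob, "occlusion_prob", 0, 1)
  if (blob_peak <= background_mean) {
    abort("`blob_peak` must exceed `background_mean`")
  }
  structure(list(arena = arena, px_per_cm = px_per_cm,
                 blob_sigma_px = blob_sigma_px, blob_peak = blob_peak,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 occlusion_prob = occlusion_prob),
            class = "scene_config")
}

#' Render a trajectory into synthetic camera frames
#'
#' One 8-bit grayscale frame per trajectory point. The marker is rendered as
#' a 2-D Gaussian centred at the true position unless the frame is occluded.
#' Image row 1 is the top of the frame while arena y points up from the
#' bottom-left corner; the conversion is handled here and in
#' [detect_marker()] symmetrically.
#'
#' @param traj Tibble with `time_s`, `x_cm`, `y_cm`; every point must lie
#'   inside the arena.
#' @param scene A [scene_config()].
#' @param seed Integer seed for noise and occlusions.
#' @return A `frame_sequence`: list with `frames` (integer matrices),
#'   `time_s`, `occluded`, `px_per_cm` and `arena`.
#' @export
render_frames <- function(traj, scene = scene_config(), seed = 1) {
  stopifnot(inherits(scene, "scene_config"))
  tr <- as_tibble(traj)
  seed <- assert_count(seed, "seed", lower = 0L)
  W <- scene$arena$width_cm; H <- scene$arena$height_cm
  if (any(tr$x_cm < 0 | tr$x_cm > W | tr$y_cm < 0 | tr$y_cm > H)) {
    abort("trajectory point outside arena: cannot render")
  }
  set.seed(seed)
  ppc <- scene$px_per_cm
  nr <- round(H * ppc); nc <- round(W * ppc)
  n <- nrow(tr)
  occluded <- runif(n) < scene$occlusion_prob
  halfw <- ceiling(5 * scene$blob_sigma_px)
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    f <- matrix(scene$background_mean, nr, nc)
    if (scene$background_sd > 0) {
      f <- f + matrix(rnorm(nr * nc, 0, scene$background_sd), nr, nc)
    }
    if (!occluded[i]) {
      cx <- tr$x_cm[i] * ppc + 0.5          # blob centre in pixel coords
      cy <- nr - tr$y_cm[i] * ppc + 0.5     # row axis points down
      rows <- max(1L, floor(cy - halfw)):min(nr, ceiling(cy + halfw))
      cols <- max(1L, floor(cx - halfw)):min(nc, ceiling(cx + halfw))
      dr <- (rows - cy); dc <- (cols - cx)
      blob <- scene$blob_peak *
        exp(-outer(dr^2, dc^2, `+`) / (2 * scene$blob_sigma_px^2))
      f[rows, cols] <- f[rows, cols] + blob
    }
    f <- matrix(as.integer(pmin(255, pmax(0, round(f)))), nr, nc)
    attr(f, "px_per_cm") <- ppc
    frames[[i]] <- f
  }
  structure(list(frames = frames, time_s = tr$time_s, occluded = occluded,
                 px_per_cm = ppc, arena = scene$arena),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("frame_sequence: %d frames of %d x %d px (%.1f px/cm), %d occluded\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              x$px_per_cm, sum(x$occluded)))
  invisible(x)
}

#' Write and read a frame sequence as PNG files
#'
#' Frames are written as 8-bit grayscale PNGs (`frame_000001.png`, ...) with
#' a plain-text sidecar `scene.txt` recording the pixel scale, arena size
#' and frame times.
#'
#' @param fs A `frame_sequence`.
#' @param dir Directory to write to (created if needed).
#' @return `write_frames()` the directory, invisibly; `read_frames()` a
#'   `frame_sequence` (with `occluded` unknown, all `FALSE`).
#' @export
write_frames <- function(fs, dir) {
  stopifnot(inherits(fs, "frame_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(fs$frames)) {
    png::writePNG(fs$frames[[i]] / 255,
                  file.path(dir, sprintf("frame_%06d.png", i)))
  }
  writeLines(c(
    sprintf("px_per_cm=%.10g", fs$px_per_cm),
    sprintf("width_cm=%.10g", fs$arena$width_cm),
    sprintf("height_cm=%.10g", fs$arena$height_cm),
    sprintf("margin_cm=%.10g", fs$arena$margin_cm),
    sprintf("frame_rate_hz=%.10g", fs$arena$frame_rate_hz),
    paste0("time_s=", paste(fs$time_s, collapse = ","))
  ), file.path(dir, "scene.txt"))
  invisible(dir)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  side <- file.path(dir, "scene.txt")
  if (!file.exists(side)) abort("missing scene.txt sidecar with pixel scale")
  kv <- strsplit(readLines(side), "=", fixed = TRUE)
  vals <- setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, "", 1))
  ppc <- as.numeric(vals$px_per_cm)
  arena <- arena_config(as.numeric(vals$width_cm), as.numeric(vals$height_cm),
                        as.numeric(vals$margin_cm),
                        as.numeric(vals$frame_rate_hz))
  files <- sort(list.files(dir, pattern = "^frame_.*\\.png$",
                           full.names = TRUE))
  frames <- lapply(files, function(fp) {
    img <- png::readPNG(fp)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    f <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
    attr(f, "px_per_cm") <- ppc
    f
  })
  times <- as.numeric(strsplit(vals$time_s, ",", fixed = TRUE)[[1]])
  structure(list(frames = frames, time_s = times,
                 occluded = rep(FALSE, length(frames)),
                 px_per_cm = ppc, arena = arena),
            class = "frame_sequence")
}
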
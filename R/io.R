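#' Write and read trial series as CSV with a JSON sidecar
#'
#' The CSV has columns `frame`, `time_s`, then one column per channel; the
#' sidecar (`<path>.json`) records framerate, onset frame, transform and
#' quantile levels so the series round-trips exactly.
#'
#' @param series a `trial_series`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_trial_series <- function(series, path) {
  stopifnot(inherits(series, "trial_series"))
  n <- nrow(series$values)
  df <- data.frame(frame = seq_len(n) - 1L,
                   time_s = (seq_len(n) - 1L) / series$framerate)
  df <- cbind(df, as.data.frame(series$values))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(framerate = series$framerate, onset_frame = series$onset_frame,
               transform = series$transform,
               quantile_levels = series$quantile_levels,
               channels = colnames(series$values))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trial_series
#' @param path CSV path written by [write_trial_series()], or any CSV whose
#'   non-`frame`/`time_s` columns are channels (metadata then falls back to
#'   `framerate`/`onset_frame` arguments).
#' @param framerate,onset_frame fallbacks when no sidecar is present.
#' @return a `trial_series`.
#' @export
read_trial_series <- function(path, framerate = 15, onset_frame = 0) {
  df <- utils::read.csv(path, check.names = FALSE)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list(framerate = framerate, onset_frame = onset_frame,
                    transform = "raw", quantile_levels = NULL)
  chans <- setdiff(names(df), c("frame", "time_s"))
  values <- as.matrix(df[chans])
  ql <- meta$quantile_levels %||%
    (as.numeric(sub("^.*q", "", chans)) / 100)
  out <- assemble_trial(list(values), onset_frame = meta$onset_frame,
                        average_cameras = TRUE, framerate = meta$framerate,
                        quantile_levels = ql)
  colnames(out$values) <- chans
  out$transform <- meta$transform %||% "raw"
  out
}

#' Export per-frame landmarks or matches as CSV
#' @param landmarks data.frame from [detect_landmarks()] or
#'   [match_landmarks()].
#' @param path output path.
#' @export
write_landmarks_csv <- function(landmarks, path) {
  df <- as.data.frame(landmarks)
  df$frame <- attr(landmarks, "frame_index") %||% NA_integer_
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read or write a frame sequence as a directory of PNGs
#'
#' Frames are 8-bit grey PNGs named `frame_0000.png`, `frame_0001.png`, ...;
#' `background.png` holds the static background. Requires the `png` package.
#'
#' @param frames list of grey matrices (0--255).
#' @param background background matrix.
#' @param dir directory (created if needed).
#' @return `dir` (write) or a list with `frames` and `background` (read).
#' @export
write_frames_png <- function(frames, background, dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stopf("the 'png' package is required for PNG I/O")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  png::writePNG(background / 255, file.path(dir, "background.png"))
  for (i in seq_along(frames))
    png::writePNG(frames[[i]] / 255,
                  file.path(dir, sprintf("frame_%04d.png", i - 1)))
  invisible(dir)
}

#' @rdname write_frames_png
#' @export
read_frames_png <- function(dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stopf("the 'png' package is required for PNG I/O")
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (length(files) == 0) stopf("no frame_*.png files in %s", dir)
  to_grey <- function(a) {
    if (length(dim(a)) == 3) a <- a[, , 1]
    a * 255
  }
  frames <- lapply(files, function(f) to_grey(png::readPNG(f)))
  bg_path <- file.path(dir, "background.png")
  background <- if (file.exists(bg_path)) to_grey(png::readPNG(bg_path)) else NULL
  list(frames = frames, background = background)
}
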
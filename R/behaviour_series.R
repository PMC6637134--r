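#' Per-frame landmark speed distribution
#'
#' Converts matched landmark pairs into the distribution of landmark speeds
#' for that frame: the Euclidean displacement of each matched landmark, in
#' px/frame.
#'
#' @param matches data.frame from [match_landmarks()] (columns `x0`, `y0`,
#'   `x1`, `y1`); rows may be pre-filtered to motion-model inliers.
#' @param framerate frames per second (recorded for unit conversion).
#' @return object of class `speed_distribution`: `speeds` (px/frame),
#'   `frame_index`, `framerate`, `empty` flag.
#' @export
landmark_speeds <- function(matches, framerate = 15) {
  fi <- attr(matches, "frame_index") %||% NA_integer_
  if (nrow(matches) == 0) {
    return(structure(list(speeds = numeric(), frame_index = fi,
                          framerate = framerate, empty = TRUE),
                     class = "speed_distribution"))
  }
  sp <- sqrt((matches$x1 - matches$x0)^2 + (matches$y1 - matches$y0)^2)
  structure(list(speeds = sp, frame_index = fi, framerate = framerate,
                 empty = FALSE),
            class = "speed_distribution")
}

#' Empirical speed quantiles for one frame
#'
#' Quantiles of the landmark speed distribution by linear interpolation of
#' order statistics (continuous estimator, `stats::quantile` type 7). An
#' empty distribution yields missing values, carried rather than raised.
#'
#' @param dist a `speed_distribution` (or bare numeric vector of speeds).
#' @param levels strictly increasing probabilities in (0, 1); default the
#'   10/30/50/70/90 percent levels.
#' @return named numeric vector, non-decreasing.
#' @export
speed_quantiles <- function(dist, levels = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  if (any(levels <= 0 | levels >= 1) || is.unsorted(levels, strictly = TRUE))
    stopf("levels must be strictly increasing within (0, 1)")
  speeds <- if (inherits(dist, "speed_distribution")) dist$speeds else dist
  nm <- paste0("q", round(levels * 100))
  if (length(speeds) == 0)
    return(stats::setNames(rep(NA_real_, length(levels)), nm))
  stats::setNames(as.numeric(quantile(speeds, probs = levels, type = 7,
                                      names = FALSE)), nm)
}

#' Assemble a trial's multivariate speed-quantile series
#'
#' Stacks per-frame quantile vectors from one or more cameras into a trial
#' time series. Channels are either kept separate per camera (for changepoint
#' detection, which runs independently on each series) or averaged across
#' cameras (for speed statistics).
#'
#' @param per_camera list of `n_frames x n_levels` matrices, one per camera
#'   (rows = frames, 0-based; columns = quantile levels).
#' @param onset_frame stimulus onset, 0-based frame.
#' @param average_cameras if `TRUE`, average matching quantile channels
#'   across cameras; if `FALSE`, stack all channels.
#' @param framerate frames per second.
#' @param quantile_levels the quantile probabilities of the columns.
#' @return object of class `trial_series`: `values` (`n_frames x n_channels`
#'   matrix with named columns), `quantile_levels`, `framerate`,
#'   `onset_frame`, `transform` (`"raw"`).
#' @export
assemble_trial <- function(per_camera, onset_frame, average_cameras = TRUE,
                           framerate = 15,
                           quantile_levels = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  if (!is.list(per_camera) || length(per_camera) == 0)
    stopf("`per_camera` must be a non-empty list of matrices")
  per_camera <- lapply(per_camera, as.matrix)
  nf <- vapply(per_camera, nrow, 0L)
  if (length(unique(nf)) != 1) stopf("cameras disagree on frame count")
  ncl <- vapply(per_camera, ncol, 0L)
  if (length(unique(ncl)) != 1 || ncl[1] != length(quantile_levels))
    stopf("cameras disagree on quantile levels")
  if (onset_frame < 0 || onset_frame >= nf[1])
    stopf("onset_frame outside recording")
  qn <- paste0("q", round(quantile_levels * 100))
  if (average_cameras) {
    values <- Reduce(`+`, per_camera) / length(per_camera)
    colnames(values) <- qn
  } else {
    values <- do.call(cbind, per_camera)
    colnames(values) <- as.vector(t(outer(seq_along(per_camera), qn,
                                          function(i, q) paste0("cam", i, "_", q))))
  }
  structure(list(values = values, quantile_levels = quantile_levels,
                 framerate = framerate, onset_frame = as.integer(onset_frame),
                 transform = "raw"),
            class = "trial_series")
}

#' @export
print.trial_series <- function(x, ...) {
  cat(sprintf("trial_series: %d frames x %d channels @ %g Hz, onset frame %d, %s\n",
              nrow(x$values), ncol(x$values), x$framerate, x$onset_frame,
              x$transform))
  invisible(x)
}

#' Truncated log transform of a trial series
#'
#' Applies `v -> ln(max(v, floor))` to every channel. Raw speed series are
#' positively skewed and bias changepoint detection toward movement
#' increases (flights); the truncated log symmetrises them so that movement
#' arrests (freezes) are detected as readily.
#'
#' @param series a `trial_series`.
#' @param floor positive truncation constant in speed units (default half a
#'   pixel per frame).
#' @return the transformed `trial_series` (transform tag `"truncated_log"`).
#' @export
truncated_log <- function(series, floor = 0.5) {
  stopifnot(inherits(series, "trial_series"))
  if (!is.finite(floor) || floor <= 0) stopf("`floor` must be > 0")
  series$values <- log(pmax(series$values, floor))
  series$transform <- "truncated_log"
  series
}

# Fill missing channel values by carrying the previous observation forward
# (and back-filling a missing head); PELT requires complete series.
bridge_missing <- function(series) {
  v <- series$values
  for (j in seq_len(ncol(v))) {
    col <- v[, j]
    if (anyNA(col)) {
      ok <- which(!is.na(col))
      if (length(ok) == 0) stopf("channel %d entirely missing", j)
      idx <- cummax(ifelse(is.na(col), 0L, seq_along(col)))
      idx[idx == 0L] <- ok[1]          # back-fill a missing head
      v[, j] <- col[idx]
    }
  }
  series$values <- v
  series
}
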
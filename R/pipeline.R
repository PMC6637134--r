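#' Pipeline configuration
#'
#' Collects every tunable parameter of the tracking, series, changepoint and
#' statistics stages with its default. Defaults follow the study protocol
#' where one is stated (15 Hz, 10-px inlier threshold, K in 1..5 with 10
#' clustering restarts, 0.6 s changepoint and 0.53 s speed windows) and
#' documented engineering choices otherwise.
#'
#' @param ... overrides for any configuration field.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # tracking
    diff_threshold = 15, opening_radius = 3, roi_pad = 5,
    n_levels = 6, scale_factor = 1.25, smooth_sigma = 1.25, smooth_taps = 13,
    harris_k = 0.04, score_frac = 0.01, merge_radius = 1,
    patch_radius = 5, search_radius = 30, min_correlation = 0.5,
    # motion model
    use_motion_model = TRUE, K_range = 1:5, n_restarts = 10,
    ransac_iterations = 200, inlier_threshold = 10, sigma_min = 0.1,
    # series
    quantile_levels = c(0.1, 0.3, 0.5, 0.7, 0.9), framerate = 15,
    transform = "raw", log_floor = 0.5,
    # changepoints
    min_seg = 1, beta = NULL, beta_range = NULL,
    # statistics
    chp_window_s = 0.6, speed_window_s = 0.53, literal_sign = FALSE,
    seed = 1)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stopf("unknown config fields: %s",
                             paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (!cfg$transform %in% c("raw", "truncated_log"))
    stopf("transform must be 'raw' or 'truncated_log'")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file holds any subset of [pipeline_config()] fields; unknown fields
#' are an error. Requires the `yaml` package.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stopf("the 'yaml' package is required to read YAML configs")
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(pipeline_config, vals)
}

#' Track one trial video into a speed-quantile series
#'
#' Runs the full tracking stage on a frame sequence: foreground extraction,
#' pyramid Harris landmarks inside the (padded) foreground box, patch
#' correlation matching between consecutive frames, MDL-selected clustered
#' rigid-motion outlier rejection, landmark speeds and per-frame speed
#' quantiles.
#'
#' @param frames list of grey-level matrices.
#' @param background the session's static background frame.
#' @param onset_frame stimulus onset, 0-based.
#' @param config a [pipeline_config()].
#' @return list with `series` (a `trial_series`, frame 0 and any unmatched
#'   frames bridged), `n_landmarks`, `n_matches`, `K_selected` per frame.
#' @export
track_trial <- function(frames, background, onset_frame,
                        config = pipeline_config()) {
  n <- length(frames)
  if (n < 2) stopf("need at least 2 frames")
  nr <- nrow(background); nc <- ncol(background)
  landmarks <- vector("list", n)
  bboxes <- vector("list", n)
  for (f in seq_len(n)) {
    fg <- compute_foreground(frames[[f]], background,
                             config$diff_threshold, config$opening_radius)
    if (fg$empty) { landmarks[[f]] <- NULL; next }
    pad <- config$roi_pad
    roi <- c(max(0, fg$bbox[1] - pad), max(0, fg$bbox[2] - pad),
             min(nc, fg$bbox[3] + pad), min(nr, fg$bbox[4] + pad))
    bboxes[[f]] <- fg$bbox
    landmarks[[f]] <- detect_landmarks(
      frames[[f]], roi, n_levels = config$n_levels,
      scale_factor = config$scale_factor, smooth_sigma = config$smooth_sigma,
      smooth_taps = config$smooth_taps, harris_k = config$harris_k,
      score_frac = config$score_frac, merge_radius = config$merge_radius,
      frame_index = f - 1L)
  }
  qmat <- matrix(NA_real_, n, length(config$quantile_levels))
  n_landmarks <- vapply(landmarks, function(l) if (is.null(l)) 0L else nrow(l), 0L)
  n_matches <- integer(n)
  K_selected <- rep(NA_integer_, n)
  for (f in 2:n) {
    lp <- landmarks[[f - 1]]; lc <- landmarks[[f]]
    if (is.null(lp) || is.null(lc) || nrow(lp) == 0 || nrow(lc) == 0) next
    pairs <- match_landmarks(lp, lc, frames[[f - 1]], frames[[f]],
                             patch_radius = config$patch_radius,
                             search_radius = config$search_radius,
                             min_correlation = config$min_correlation,
                             frame_index = f - 1L)
    n_matches[f] <- nrow(pairs)
    if (nrow(pairs) < 4) next
    if (config$use_motion_model) {
      bb <- bboxes[[f - 1]] %||% bboxes[[f]]
      area <- max(1, (bb[3] - bb[1]) * (bb[4] - bb[2]))
      mod <- tryCatch(
        select_motion_model(pairs, K_range = config$K_range,
                            n_restarts = config$n_restarts,
                            inlier_threshold = config$inlier_threshold,
                            seed = child_seed(config$seed, f),
                            bbox_area = area,
                            ransac_iterations = config$ransac_iterations,
                            sigma_min = config$sigma_min),
        error = function(e) NULL)
      if (!is.null(mod)) {
        K_selected[f] <- mod$K
        pairs <- pairs[mod$labels > 0, , drop = FALSE]
      }
    }
    if (nrow(pairs) == 0) next
    sp <- landmark_speeds(pairs, framerate = config$framerate)
    qmat[f, ] <- speed_quantiles(sp, config$quantile_levels)
  }
  series <- assemble_trial(list(qmat), onset_frame,
                           average_cameras = TRUE,
                           framerate = config$framerate,
                           quantile_levels = config$quantile_levels)
  series <- bridge_missing(series)
  list(series = series, n_landmarks = n_landmarks, n_matches = n_matches,
       K_selected = K_selected)
}

# Default CROPS penalty range for one channel: from a fraction of the
# MAD-based noise scale of first differences up to n * var(y).
default_beta_range <- function(y) {
  sigma2 <- (stats::mad(diff(y)) / sqrt(2))^2
  lo <- max(1e-6, 0.1 * sigma2)
  hi <- max(lo * 10, length(y) * stats::var(y))
  c(lo, hi)
}

#' Estimate the penalty knee for one trial
#'
#' Runs [crops_path()] and [fit_knee()] on each channel of a trial series
#' and returns the median of the converged per-channel knees.
#'
#' @param series a `trial_series`.
#' @param min_seg minimum segment length.
#' @param beta_range optional `(beta_min, beta_max)`; by default derived per
#'   channel from the data.
#' @return list with `knee` (scalar, `NA` when no channel converged) and
#'   `per_channel` (a `knee_fit` or `NULL` per channel).
#' @export
trial_knee <- function(series, min_seg = 1, beta_range = NULL) {
  stopifnot(inherits(series, "trial_series"))
  fits <- vector("list", ncol(series$values))
  for (j in seq_len(ncol(series$values))) {
    y <- series$values[, j]
    br <- beta_range %||% default_beta_range(y)
    fits[[j]] <- tryCatch({
      path <- crops_path(y, br[1], br[2], min_seg = min_seg)
      fit_knee(path)
    }, error = function(e) NULL)
  }
  psis <- vapply(fits, function(f)
    if (!is.null(f) && isTRUE(f$converged)) f$psi else NA_real_, 0)
  knee <- if (all(is.na(psis))) NA_real_ else median(psis, na.rm = TRUE)
  list(knee = knee, per_channel = fits)
}

#' Segment every channel of a trial and pool the changepoints
#'
#' @param series a `trial_series`.
#' @param beta penalty applied to every channel.
#' @param min_seg minimum segment length.
#' @return list with `segmentations` (per channel) and `pooled`
#'   ([pool_changepoints()] counts).
#' @export
segment_trial <- function(series, beta, min_seg = 1) {
  stopifnot(inherits(series, "trial_series"))
  segs <- lapply(seq_len(ncol(series$values)), function(j)
    pelt_segment(series$values[, j], beta, min_seg = min_seg))
  list(segmentations = segs,
       pooled = pool_changepoints(segs, nrow(series$values)))
}

#' Run the full analysis pipeline over a batch of trials
#'
#' Each trial is either a video (`frames` + `background`) or a pre-tracked
#' series (`series`, a `trial_series`). Videos are tracked into
#' speed-quantile series; the configured transform is applied for
#' changepoint detection (speed responses always use the raw series); the
#' penalty is `config$beta`, or chosen automatically as the median of the
#' per-trial CROPS knees; every channel is segmented with PELT, changepoints
#' are pooled, and trial-level statistics are assembled.
#'
#' @param trials non-empty list; each element a list with either `frames`
#'   and `background`, or `series`, plus optional `onset_frame`,
#'   `stimulus_label`, `block_index`, `animal`. An element may also be a
#'   zero-argument function returning such a list; it is called when the
#'   trial is processed and its frames are released afterwards, so a long
#'   session never holds more than one trial's video in memory.
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: `trials` (data.frame with one
#'   row per trial: `delta_chp_rate`, `speed_delta`, `classification`, ...),
#'   `beta`, `knees`, `series`, `segmented`, `summary`
#'   (per-stimulus [response_table()]), `sign_test_speed`.
#' @export
run_pipeline <- function(trials, config = pipeline_config()) {
  if (!is.list(trials) || length(trials) == 0) stopf("empty trial list")
  n_tr <- length(trials)
  series_raw <- vector("list", n_tr)
  tracking <- vector("list", n_tr)
  meta <- vector("list", n_tr)
  for (i in seq_len(n_tr)) {
    tr <- trials[[i]]
    if (is.function(tr)) tr <- tr()
    meta[[i]] <- tr[c("onset_frame", "stimulus_label", "block_index",
                      "animal", "trial_index")]
    if (!is.null(tr$series)) {
      series_raw[[i]] <- tr$series
    } else if (!is.null(tr$frames)) {
      onset <- tr$onset_frame %||% stopf("trial %d: onset_frame required", i)
      tk <- track_trial(tr$frames, tr$background, onset, config)
      series_raw[[i]] <- tk$series
      tracking[[i]] <- tk[c("n_landmarks", "n_matches", "K_selected")]
    } else stopf("trial %d has neither frames nor series", i)
    rm(tr)
  }
  series_cp <- lapply(series_raw, function(s)
    if (config$transform == "truncated_log")
      truncated_log(s, floor = config$log_floor) else s)
  knees <- rep(NA_real_, n_tr)
  beta <- config$beta
  if (is.null(beta)) {
    for (i in seq_len(n_tr))
      knees[i] <- trial_knee(series_cp[[i]], min_seg = config$min_seg,
                             beta_range = config$beta_range)$knee
    beta <- choose_penalty(knees[is.finite(knees)])
  }
  segmented <- lapply(series_cp, segment_trial, beta = beta,
                      min_seg = config$min_seg)
  rows <- vector("list", n_tr)
  for (i in seq_len(n_tr)) {
    tr <- meta[[i]]
    s <- series_raw[[i]]
    onset <- tr$onset_frame %||% s$onset_frame
    delta <- changepoint_rate_delta(segmented[[i]]$pooled, onset,
                                    window_s = config$chp_window_s,
                                    framerate = s$framerate,
                                    literal_sign = config$literal_sign)
    spd <- speed_response(s, onset, window_s = config$speed_window_s,
                          literal_sign = config$literal_sign)
    rows[[i]] <- data.frame(
      trial_index = tr$trial_index %||% i,
      animal = tr$animal %||% NA_character_,
      stimulus_label = tr$stimulus_label %||% "stimulus",
      block_index = tr$block_index %||% NA_integer_,
      onset_frame = onset,
      delta_chp_rate = delta,
      speed_delta = spd,
      n_changepoints = sum(unclass(segmented[[i]]$pooled)),
      classification = classify_trial(delta))
  }
  trial_table <- do.call(rbind, rows)
  structure(list(trials = trial_table, beta = beta, knees = knees,
                 series = series_raw, series_transformed = series_cp,
                 segmented = segmented, tracking = tracking,
                 summary = response_table(trial_table),
                 sign_test_speed = sign_test(trial_table$speed_delta)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d trials, beta = %.4g\n", nrow(x$trials), x$beta))
  print(x$summary)
  cat(sprintf("sign test on speed responses: p = %.4g (n = %d)\n",
              x$sign_test_speed$p, x$sign_test_speed$n_nonzero))
  invisible(x)
}
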
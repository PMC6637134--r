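window_frames <- function(window_s, framerate) {
  w <- round(window_s * framerate)
  if (w < 1) stopf("window shorter than one frame")
  as.integer(w)
}

#' Stimulus-aligned difference in pooled changepoint rate
#'
#' The trial-level response statistic: pooled changepoint counts are summed
#' in equal windows before and after stimulus onset (pre window ends at
#' `onset_frame - 1`, post window starts at `onset_frame`) and converted to
#' rates. Positive values mean the changepoint rate increased after the
#' stimulus; `literal_sign = TRUE` returns pre minus post instead.
#'
#' @param pooled integer vector of pooled changepoint counts (one per frame).
#' @param onset_frame stimulus onset, 0-based frame.
#' @param window_s window length in seconds (default 0.6).
#' @param framerate frames per second.
#' @param literal_sign return `pre - post` instead of `post - pre`.
#' @return changepoints per second.
#' @export
changepoint_rate_delta <- function(pooled, onset_frame, window_s = 0.6,
                                   framerate = 15, literal_sign = FALSE) {
  w <- window_frames(window_s, framerate)
  n <- length(pooled)
  if (onset_frame - w < 0 || onset_frame + w > n)
    stopf("window exceeds recording")
  dur <- w / framerate
  pre <- sum(pooled[(onset_frame - w + 1):onset_frame]) / dur
  post <- sum(pooled[(onset_frame + 1):(onset_frame + w)]) / dur
  if (literal_sign) pre - post else post - pre
}

#' Stimulus-aligned speed response
#'
#' Mean of the (camera-averaged) speed-quantile channels over a post-onset
#' window minus the same over the pre-onset window; positive values mean a
#' movement increase after the stimulus.
#'
#' @param series a `trial_series`.
#' @param onset_frame stimulus onset; defaults to the series' own.
#' @param window_s window length in seconds (default 0.53).
#' @param literal_sign return `pre - post` instead of `post - pre`.
#' @return speed response in the series' units.
#' @export
speed_response <- function(series, onset_frame = NULL, window_s = 0.53,
                           literal_sign = FALSE) {
  stopifnot(inherits(series, "trial_series"))
  onset_frame <- onset_frame %||% series$onset_frame
  w <- window_frames(window_s, series$framerate)
  n <- nrow(series$values)
  if (onset_frame - w < 0 || onset_frame + w > n)
    stopf("window exceeds recording")
  pre <- mean(series$values[(onset_frame - w + 1):onset_frame, ], na.rm = TRUE)
  post <- mean(series$values[(onset_frame + 1):(onset_frame + w), ], na.rm = TRUE)
  if (literal_sign) pre - post else post - pre
}

#' Classify a trial by the sign of its changepoint-rate response
#' @param delta_chp_rate finite scalar.
#' @return `"increase"`, `"decrease"` or `"none"` (exact zero).
#' @export
classify_trial <- function(delta_chp_rate) {
  if (!is.finite(delta_chp_rate)) stopf("delta must be finite")
  if (delta_chp_rate > 0) "increase"
  else if (delta_chp_rate < 0) "decrease"
  else "none"
}

#' Exact two-sided sign test
#'
#' Tests whether response deltas are symmetrically signed: exact zeros are
#' dropped, and with `k` positives among `n` nonzero values,
#' `p = min(1, 2 * min(P(X <= k), P(X >= k)))` for `X ~ Binomial(n, 1/2)`.
#'
#' @param deltas numeric vector.
#' @return list with `p`, `n_nonzero`, `n_positive`, `all_zero` flag.
#' @export
sign_test <- function(deltas) {
  deltas <- deltas[is.finite(deltas)]
  nz <- deltas[deltas != 0]
  n <- length(nz)
  if (n == 0) return(list(p = 1, n_nonzero = 0L, n_positive = 0L,
                          all_zero = TRUE))
  k <- sum(nz > 0)
  p_lo <- pbinom(k, n, 0.5)
  p_hi <- pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  list(p = min(1, 2 * min(p_lo, p_hi)), n_nonzero = n, n_positive = k,
       all_zero = FALSE)
}

#' Permutation test for habituation across repeated trials
#'
#' Compares responses on early repetitions of a stimulus (by default the 1st
#' and 2nd) against late repetitions (6th and 7th): the statistic is
#' `mean(early) - mean(late)`, its null distribution is built by shuffling
#' the repetition labels (within animal when `animal` is given), and the
#' one-sided p-value is the fraction of shuffled statistics at least as large
#' as the observed one.
#'
#' @param values per-trial response values.
#' @param trial_order repetition index of each trial (1 = first
#'   presentation).
#' @param early_set,late_set repetition indices defining the two groups.
#' @param n_perm number of shuffles (default 100000).
#' @param seed optional integer seed.
#' @param animal optional per-trial animal id; shuffling is stratified
#'   within animal.
#' @return list with `observed_diff`, `p`, `n_perm`.
#' @export
habituation_permutation_test <- function(values, trial_order,
                                         early_set = c(1, 2),
                                         late_set = c(6, 7),
                                         n_perm = 100000, seed = NULL,
                                         animal = NULL) {
  if (length(values) != length(trial_order)) stopf("length mismatch")
  if (n_perm < 1) stopf("n_perm must be >= 1")
  if (is.null(animal)) animal <- rep(1L, length(values))
  stat <- function(ord) {
    e <- values[ord %in% early_set]
    l <- values[ord %in% late_set]
    if (length(e) == 0 || length(l) == 0) stopf("degenerate group")
    mean(e) - mean(l)
  }
  observed <- stat(trial_order)
  groups <- split(seq_along(values), animal)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    ord <- trial_order
    for (g in groups) ord[g] <- trial_order[g][sample.int(length(g))]
    stat(ord)
  }, 0))
  list(observed_diff = observed, p = mean(perm >= observed), n_perm = n_perm)
}

#' Summarise trial responses by stimulus
#'
#' @param trials data.frame with columns `stimulus_label`, `delta_chp_rate`,
#'   `speed_delta`, `classification` (e.g. from [run_pipeline()]).
#' @param group_by grouping column (default `"stimulus_label"`).
#' @return data.frame with per-group `n`, percentage of
#'   increase/decrease/none trials, and mean and standard error of the
#'   changepoint-rate and speed responses.
#' @export
response_table <- function(trials, group_by = "stimulus_label") {
  if (nrow(trials) == 0) stopf("no trials")
  groups <- split(trials, trials[[group_by]])
  rows <- lapply(names(groups), function(g) {
    tr <- groups[[g]]
    n <- nrow(tr)
    cls <- tr$classification
    sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
    data.frame(group = g, n = n,
               pct_increase = 100 * mean(cls == "increase"),
               pct_decrease = 100 * mean(cls == "decrease"),
               pct_none = 100 * mean(cls == "none"),
               mean_delta_chp = mean(tr$delta_chp_rate),
               sem_delta_chp = sem(tr$delta_chp_rate),
               mean_speed_delta = mean(tr$speed_delta),
               sem_speed_delta = sem(tr$speed_delta))
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- group_by
  out
}

#' Block-randomised stimulus protocol
#'
#' Builds the trial order of a session: `n_blocks` blocks of the given
#' stimuli, order independently randomised within each block, with a fixed
#' inter-stimulus interval.
#'
#' @param stimuli character vector of stimulus labels per block.
#' @param n_blocks number of blocks (default 7).
#' @param isi_s inter-stimulus interval, seconds (default 73).
#' @param pre_s,post_s recorded window around each onset, seconds (defaults
#'   6 and 7).
#' @param framerate frames per second (default 15).
#' @param seed optional integer seed for the block randomisation.
#' @return data.frame with `block_index`, `stimulus_label`, `trial_index`,
#'   `repetition` (per-stimulus count), `onset_s`, `onset_frame` (within the
#'   trial recording).
#' @export
protocol_spec <- function(stimuli, n_blocks = 7, isi_s = 73, pre_s = 6,
                          post_s = 7, framerate = 15, seed = NULL) {
  if (length(stimuli) < 1) stopf("need at least one stimulus")
  order_all <- with_seed(seed, unlist(lapply(seq_len(n_blocks), function(b)
    sample(stimuli))))
  n <- length(order_all)
  out <- data.frame(block_index = rep(seq_len(n_blocks), each = length(stimuli)),
                    stimulus_label = order_all,
                    trial_index = seq_len(n),
                    onset_s = (seq_len(n) - 1) * isi_s + pre_s,
                    onset_frame = as.integer(round(pre_s * framerate)))
  out$repetition <- stats::ave(rep(1L, n), out$stimulus_label,
                               FUN = cumsum)
  out
}
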
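#' Extract the animal foreground by background subtraction
#'
#' Thresholds the absolute difference between a frame and the session's static
#' background, then applies a morphological opening (erosion followed by
#' dilation) with a disc structuring element to remove small debris such as
#' droppings, and returns the tight bounding box of the remaining pixels.
#'
#' @param frame,background numeric grey-level matrices of identical shape.
#' @param diff_threshold absolute grey-level difference counted as foreground.
#' @param opening_radius radius (px) of the disc structuring element; 0 skips
#'   the opening.
#' @return list with `mask` (logical matrix), `bbox` (`(x0, y0, x1, y1)`,
#'   0-based half-open, or `NULL`) and `empty` flag.
#' @export
compute_foreground <- function(frame, background, diff_threshold = 15,
                               opening_radius = 3) {
  if (!all(dim(frame) == dim(background)))
    stopf("frame and background shapes differ")
  mask <- abs(frame - background) > diff_threshold
  if (opening_radius > 0 && any(mask)) {
    brush <- EBImage::makeBrush(2L * as.integer(opening_radius) + 1L, "disc")
    mask <- EBImage::opening(mask * 1, brush) > 0.5
  }
  if (!any(mask)) return(list(mask = mask, bbox = NULL, empty = TRUE))
  idx <- which(mask, arr.ind = TRUE)
  # rows are y, cols are x; 0-based half-open box
  bbox <- c(min(idx[, 2]) - 1L, min(idx[, 1]) - 1L, max(idx[, 2]), max(idx[, 1]))
  list(mask = mask, bbox = as.integer(bbox), empty = FALSE)
}

# 1-D Gaussian taps, unit sum.
gauss_taps <- function(n, sigma) {
  x <- seq(-(n - 1) / 2, (n - 1) / 2)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Replicate-pad a matrix by pr rows / pc cols on each side.
pad_replicate <- function(m, pr, pc) {
  ri <- c(rep(1L, pr), seq_len(nrow(m)), rep(nrow(m), pr))
  ci <- c(rep(1L, pc), seq_len(ncol(m)), rep(ncol(m), pc))
  m[ri, ci, drop = FALSE]
}

# Separable convolution by shift-and-add with replicate boundary; taps_r runs
# along rows (y), taps_c along columns (x). Fast for the small ROIs the
# tracker works on.
sepconv <- function(img, taps_r, taps_c = taps_r) {
  hr <- (length(taps_r) - 1L) %/% 2L
  hc <- (length(taps_c) - 1L) %/% 2L
  p <- pad_replicate(img, hr, hc)
  nr <- nrow(img); nc <- ncol(img)
  if (hr > 0) {
    acc <- 0
    for (k in seq_along(taps_r))
      acc <- acc + taps_r[k] * p[(k - 1) + seq_len(nr), , drop = FALSE]
    p <- acc
  } else p <- p[seq_len(nr) + 0, , drop = FALSE]
  if (hc > 0) {
    acc <- 0
    for (k in seq_along(taps_c))
      acc <- acc + taps_c[k] * p[, (k - 1) + seq_len(nc), drop = FALSE]
    p <- acc
  }
  p
}

smooth_img <- function(img, taps) {
  sepconv(img, taps, taps)
}

# Harris corner response and 3x3 non-max suppression on one image.
# Returns data.frame(x, y, score) in 0-based pixel coordinates of `img`.
harris_corners <- function(img, k = 0.04, score_frac = 0.01,
                           window_sigma = 1.25, window_taps = 7) {
  nr <- nrow(img); nc <- ncol(img)
  if (nr < window_taps || nc < window_taps)
    return(data.frame(x = numeric(), y = numeric(), score = numeric()))
  d <- c(-0.5, 0, 0.5)                  # central difference
  gx <- sepconv(img, 1, d)              # derivative along columns (x)
  gy <- sepconv(img, d, 1)
  w <- gauss_taps(window_taps, window_sigma)
  sxx <- smooth_img(gx * gx, w)
  syy <- smooth_img(gy * gy, w)
  sxy <- smooth_img(gx * gy, w)
  R <- sxx * syy - sxy^2 - k * (sxx + syy)^2
  mx <- max(R)
  if (!is.finite(mx) || mx <= 1e-8) return(data.frame(x = numeric(), y = numeric(), score = numeric()))
  thr <- score_frac * mx
  # 3x3 local maxima, excluding a 1-px border
  inner <- R[2:(nr - 1), 2:(nc - 1)]
  is_max <- inner >= thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & inner >= R[2:(nr - 1) + dr, 2:(nc - 1) + dc]
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(data.frame(x = numeric(), y = numeric(), score = numeric()))
  data.frame(x = idx[, 2], y = idx[, 1],               # +1 border −1 to 0-based
             score = inner[idx])
}

#' Detect body landmarks with a Harris-corner image pyramid
#'
#' Runs the Harris detector at each of `n_levels` levels of a Gaussian image
#' pyramid (13-tap smoothing, sigma 1.25, downsampling factor 1.25 per level)
#' restricted to a region of interest, maps detections back to base-image
#' coordinates by multiplying by `1.25^level`, and merges duplicates closer
#' than `merge_radius` px keeping the higher score.
#'
#' @param frame grey-level matrix.
#' @param roi `(x0, y0, x1, y1)` 0-based half-open region, e.g. a foreground
#'   bounding box (optionally padded); `NULL` uses the whole frame.
#' @param n_levels pyramid levels (level 0 = base image).
#' @param scale_factor per-level downsampling factor.
#' @param smooth_sigma,smooth_taps Gaussian smoothing before each downsample.
#' @param harris_k Harris sensitivity constant.
#' @param score_frac per-level score threshold as a fraction of the level's
#'   maximum response.
#' @param merge_radius duplicate-merging radius, base px.
#' @param frame_index optional frame label attached to the result.
#' @return data.frame with columns `x`, `y` (base-image 0-based), `level`,
#'   `score`; attribute `frame_index`.
#' @export
detect_landmarks <- function(frame, roi = NULL, n_levels = 6,
                             scale_factor = 1.25, smooth_sigma = 1.25,
                             smooth_taps = 13, harris_k = 0.04,
                             score_frac = 0.01, merge_radius = 1,
                             frame_index = NA_integer_) {
  nr <- nrow(frame); nc <- ncol(frame)
  if (is.null(roi)) roi <- c(0L, 0L, nc, nr)
  if (roi[1] < 0 || roi[2] < 0 || roi[3] > nc || roi[4] > nr ||
      roi[3] <= roi[1] || roi[4] <= roi[2])
    stopf("roi outside frame or empty")
  img <- frame[(roi[2] + 1):roi[4], (roi[1] + 1):roi[3], drop = FALSE]
  taps <- gauss_taps(smooth_taps, smooth_sigma)
  out <- vector("list", n_levels)
  for (l in seq_len(n_levels) - 1L) {
    if (l > 0) {
      if (min(dim(img)) < smooth_taps) break
      img <- smooth_img(img, taps)
      new_r <- round(nrow(img) / scale_factor)
      new_c <- round(ncol(img) / scale_factor)
      if (new_r < 7 || new_c < 7) break
      img <- EBImage::resize(img, w = new_r, h = new_c)
    }
    det <- harris_corners(img, k = harris_k, score_frac = score_frac)
    if (nrow(det) > 0) {
      det$x <- det$x * scale_factor^l + roi[1]
      det$y <- det$y * scale_factor^l + roi[2]
      det$level <- l
      out[[l + 1]] <- det
    }
  }
  det <- do.call(rbind, out)
  if (is.null(det) || nrow(det) == 0) {
    det <- data.frame(x = numeric(), y = numeric(), score = numeric(),
                      level = integer())
  } else {
    det <- det[order(-det$score), , drop = FALSE]
    keep <- rep(TRUE, nrow(det))
    for (i in seq_len(nrow(det))[-1]) {
      d2 <- (det$x[seq_len(i - 1)] - det$x[i])^2 +
            (det$y[seq_len(i - 1)] - det$y[i])^2
      if (any(keep[seq_len(i - 1)] & d2 <= merge_radius^2)) keep[i] <- FALSE
    }
    det <- det[keep, , drop = FALSE]
    rownames(det) <- NULL
  }
  det <- det[, c("x", "y", "level", "score")]
  attr(det, "frame_index") <- frame_index
  det
}

# Extract centred intensity patches around rounded landmark positions.
# Returns list(mat = (side^2 x n) matrix, ok = logical keep flags).
extract_patches <- function(frame, pts, patch_radius) {
  nr <- nrow(frame); nc <- ncol(frame)
  side <- 2L * patch_radius + 1L
  xi <- round(pts$x); yi <- round(pts$y)
  ok <- xi - patch_radius >= 0 & xi + patch_radius <= nc - 1 &
        yi - patch_radius >= 0 & yi + patch_radius <= nr - 1
  mat <- matrix(NA_real_, side * side, nrow(pts))
  for (i in which(ok)) {
    mat[, i] <- as.vector(frame[(yi[i] - patch_radius + 1):(yi[i] + patch_radius + 1),
                                (xi[i] - patch_radius + 1):(xi[i] + patch_radius + 1)])
  }
  list(mat = mat, ok = ok)
}

#' Match landmarks across consecutive frames by patch correlation
#'
#' For every landmark of the previous frame, candidate landmarks of the
#' current frame within `search_radius` px are ranked by the Pearson
#' correlation of centred intensity patches; pairs are assigned greedily by
#' best correlation (ties broken by smaller displacement), each landmark used
#' at most once, and pairs below `min_correlation` are dropped. Landmarks
#' whose patch would leave the image are skipped.
#'
#' @param prev,curr landmark data.frames from [detect_landmarks()].
#' @param prev_frame,curr_frame the corresponding grey-level frames.
#' @param patch_radius patch half-side, px (patch side `2*patch_radius+1`).
#' @param search_radius maximum displacement considered, base px.
#' @param min_correlation minimum accepted Pearson correlation.
#' @param frame_index optional label for the *current* frame.
#' @return data.frame with columns `x0`, `y0`, `x1`, `y1`, `correlation`;
#'   attribute `frame_index`.
#' @export
match_landmarks <- function(prev, curr, prev_frame, curr_frame,
                            patch_radius = 5, search_radius = 30,
                            min_correlation = 0.5, frame_index = NA_integer_) {
  empty <- data.frame(x0 = numeric(), y0 = numeric(), x1 = numeric(),
                      y1 = numeric(), correlation = numeric())
  attr(empty, "frame_index") <- frame_index
  if (nrow(prev) == 0 || nrow(curr) == 0) return(empty)
  pp <- extract_patches(prev_frame, prev, patch_radius)
  pc <- extract_patches(curr_frame, curr, patch_radius)
  pi <- which(pp$ok); ci <- which(pc$ok)
  if (length(pi) == 0 || length(ci) == 0) return(empty)
  cors <- suppressWarnings(stats::cor(pp$mat[, pi, drop = FALSE],
                                      pc$mat[, ci, drop = FALSE]))
  d2 <- outer(prev$x[pi], curr$x[ci], "-")^2 + outer(prev$y[pi], curr$y[ci], "-")^2
  valid <- is.finite(cors) & cors >= min_correlation & d2 <= search_radius^2
  cors[!valid] <- -Inf
  pairs <- list()
  while (any(is.finite(cors)) && max(cors) > -Inf) {
    best <- max(cors)
    cand <- which(cors == best, arr.ind = TRUE)
    if (nrow(cand) > 1) cand <- cand[which.min(d2[cand]), , drop = FALSE]
    r <- cand[1, 1]; cl <- cand[1, 2]
    pairs[[length(pairs) + 1]] <- c(pi[r], ci[cl], best)
    cors[r, ] <- -Inf
    cors[, cl] <- -Inf
  }
  if (length(pairs) == 0) return(empty)
  m <- do.call(rbind, pairs)
  out <- data.frame(x0 = prev$x[m[, 1]], y0 = prev$y[m[, 1]],
                    x1 = curr$x[m[, 2]], y1 = curr$y[m[, 2]],
                    correlation = m[, 3])
  attr(out, "frame_index") <- frame_index
  out
}

#' Track the body centre as the median foreground coordinate
#'
#' Baseline whole-body tracker: background subtraction and opening as in
#' [compute_foreground()], then the body centre is the per-axis median of the
#' remaining pixel positions.
#'
#' @inheritParams compute_foreground
#' @return `(x, y)` in 0-based px, or `c(NA, NA)` when no foreground remains.
#' @export
track_centroid <- function(frame, background, diff_threshold = 15,
                           opening_radius = 3) {
  fg <- compute_foreground(frame, background, diff_threshold, opening_radius)
  if (fg$empty) return(c(x = NA_real_, y = NA_real_))
  idx <- which(fg$mask, arr.ind = TRUE)
  c(x = median(idx[, 2]) - 1, y = median(idx[, 1]) - 1)
}
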
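#' Generate a piecewise-constant-mean series with known changepoints
#'
#' Draws a Gaussian series whose mean is piecewise constant, the standard
#' ground-truth signal for penalised changepoint detection.
#'
#' @param means numeric vector of per-segment means.
#' @param lengths integer vector of per-segment lengths (same length as
#'   `means`, all positive).
#' @param noise_sd standard deviation of additive Gaussian noise (>= 0).
#' @param seed optional integer seed; fixed seed gives bit-identical output.
#' @return list with `series` (numeric, length `sum(lengths)`) and
#'   `changepoints` (0-based last index of each non-final segment).
#' @examples
#' g <- generate_piecewise_series(c(0, 10), c(5, 5))
#' g$changepoints  # 4
#' @export
generate_piecewise_series <- function(means, lengths, noise_sd = 0, seed = NULL) {
  if (length(means) != length(lengths) || length(means) < 1)
    stopf("`means` and `lengths` must be non-empty and of equal length")
  if (any(lengths < 1) || any(lengths != round(lengths)))
    stopf("`lengths` must be positive integers")
  if (!is.finite(noise_sd) || noise_sd < 0) stopf("`noise_sd` must be >= 0")
  n <- sum(lengths)
  if (n < 2) stopf("total series length must be >= 2")
  series <- rep(means, times = lengths)
  if (noise_sd > 0)
    series <- series + with_seed(seed, rnorm(n, sd = noise_sd))
  cps <- cumsum(lengths)
  cps <- cps[-length(cps)] - 1L  # 0-based last index of each non-final segment
  list(series = as.numeric(series), changepoints = as.integer(cps))
}

#' Generate a rigid-motion landmark cloud with known cluster labels
#'
#' Simulates matched landmark pairs between two frames: points are placed in a
#' bounding box, each cluster moves by its own rotation+translation, isotropic
#' Gaussian noise is added, and a fraction of points are replaced by gross
#' outliers (uniform relocation in the box). Ground truth for RANSAC partial
#' Procrustes fitting and MDL cluster selection.
#'
#' @param n_points total number of landmark pairs.
#' @param clusters list of clusters, each a list with `rotation` (degrees),
#'   `translation` (length-2 px vector) and `weight`; weights must sum to 1.
#' @param noise_sd isotropic Gaussian displacement noise, px.
#' @param outlier_fraction fraction of points displaced uniformly in the box
#'   (in `[0, 1)`).
#' @param bbox `(width, height)` of the box, px.
#' @param seed optional integer seed.
#' @param cluster_boxes optional list of per-cluster `(x0, y0, x1, y1)`
#'   sub-boxes; spatially separated clusters are needed when cluster labels
#'   are to be recovered from coordinates alone.
#' @return list with `points_t`, `points_t1` (n x 2 matrices), `labels`
#'   (integer cluster id, 0 = outlier) and `transforms` (the true
#'   [rigid_transform()] per cluster).
#' @export
generate_rigid_motion_cloud <- function(n_points, clusters, noise_sd = 0,
                                        outlier_fraction = 0,
                                        bbox = c(100, 100), seed = NULL,
                                        cluster_boxes = NULL) {
  if (length(clusters) < 1) stopf("`clusters` must be non-empty")
  w <- vapply(clusters, function(cl) cl$weight %||% (1 / length(clusters)), 0)
  if (abs(sum(w) - 1) > 1e-8) stopf("cluster weights must sum to 1")
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stopf("`outlier_fraction` must be in [0, 1)")
  with_seed(seed, {
    # deterministic cluster sizes closest to the weights
    sizes <- floor(w * n_points)
    rem <- n_points - sum(sizes)
    if (rem > 0) {
      extra <- order(w * n_points - sizes, decreasing = TRUE)[seq_len(rem)]
      sizes[extra] <- sizes[extra] + 1L
    }
    labels <- rep(seq_along(clusters), times = sizes)
    pts <- matrix(0, n_points, 2)
    for (i in seq_along(clusters)) {
      idx <- which(labels == i)
      box <- if (!is.null(cluster_boxes)) cluster_boxes[[i]] else c(0, 0, bbox)
      pts[idx, 1] <- runif(length(idx), box[1], box[3])
      pts[idx, 2] <- runif(length(idx), box[2], box[4])
    }
    transforms <- lapply(clusters, function(cl)
      rigid_transform(cl$rotation * pi / 180, cl$translation))
    pts1 <- pts
    for (i in seq_along(clusters)) {
      idx <- which(labels == i)
      pts1[idx, ] <- apply_rigid(transforms[[i]], pts[idx, , drop = FALSE])
    }
    if (noise_sd > 0)
      pts1 <- pts1 + matrix(rnorm(2 * n_points, sd = noise_sd), n_points, 2)
    n_out <- round(outlier_fraction * n_points)
    if (n_out > 0) {
      out_idx <- sample.int(n_points, n_out)
      pts1[out_idx, 1] <- runif(n_out, 0, bbox[1])
      pts1[out_idx, 2] <- runif(n_out, 0, bbox[2])
      labels[out_idx] <- 0L
    }
    list(points_t = pts, points_t1 = pts1, labels = as.integer(labels),
         transforms = transforms)
  })
}

#' Build a behaviour script for the synthetic trial renderer
#'
#' A script tiles the trial's frames with behavioural segments. Modes:
#' `still`/`freeze` (no movement), `locomote`/`flight` (whole-body translation
#' at `velocity` px/frame), `head_move` (anterior 40% of the body rotates at
#' `part_velocity` deg/frame about the body centre while the rest is static).
#'
#' @param segments data.frame with columns `start`, `end` (frames, 0-based,
#'   half-open), `mode`, and optionally `vx`, `vy` (px/frame) and
#'   `part_velocity` (deg/frame).
#' @param arena_size `(width, height)` px.
#' @param framerate frames per second.
#' @return object of class `behaviour_script`.
#' @export
behaviour_script <- function(segments, arena_size = c(400, 400), framerate = 15) {
  needed <- c("start", "end", "mode")
  if (!all(needed %in% names(segments))) stopf("segments need columns start/end/mode")
  segments <- segments[order(segments$start), , drop = FALSE]
  if (segments$start[1] != 0) stopf("segments must start at frame 0")
  if (nrow(segments) > 1 &&
      any(segments$start[-1] != segments$end[-nrow(segments)]))
    stopf("segments must tile frames without gaps or overlap")
  if (any(segments$end <= segments$start)) stopf("empty segment")
  modes <- c("still", "locomote", "head_move", "flight", "freeze")
  if (!all(segments$mode %in% modes))
    stopf("unknown mode; use one of %s", paste(modes, collapse = ", "))
  for (col in c("vx", "vy", "part_velocity"))
    if (is.null(segments[[col]])) segments[[col]] <- 0
  if (!all(is.finite(as.matrix(segments[c("vx", "vy", "part_velocity")]))))
    stopf("velocities must be finite")
  if (framerate <= 0) stopf("framerate must be > 0")
  structure(list(segments = segments, arena_size = arena_size,
                 framerate = framerate,
                 n_frames = segments$end[nrow(segments)]),
            class = "behaviour_script")
}

#' Convenience scripts: locomotion that stops (freeze) or erupts (flight)
#'
#' Emulates the two canonical innate defensive responses: an animal moving at
#' `speed` px/frame that freezes shortly after stimulus onset, or a quiescent
#' animal that takes flight. The response begins `latency_frames` after onset
#' (default 2 frames = 0.13 s at 15 Hz, a realistic motor latency).
#'
#' @param n_frames trial length in frames.
#' @param onset_frame stimulus onset (0-based frame).
#' @param latency_frames motor latency between onset and behaviour change.
#' @param speed locomotion speed, px/frame.
#' @param flight_speed flight speed, px/frame.
#' @param direction unit-normalised heading for locomotion.
#' @param arena_size,framerate passed to [behaviour_script()].
#' @return a `behaviour_script`.
#' @rdname canned_scripts
#' @export
freeze_script <- function(n_frames = 200, onset_frame = 90, latency_frames = 2,
                          speed = 2, direction = c(1, 0.4),
                          arena_size = c(400, 400), framerate = 15) {
  d <- direction / sqrt(sum(direction^2))
  change <- onset_frame + latency_frames
  behaviour_script(data.frame(
    start = c(0, change), end = c(change, n_frames),
    mode = c("locomote", "freeze"),
    vx = c(speed * d[1], 0), vy = c(speed * d[2], 0)),
    arena_size = arena_size, framerate = framerate)
}

#' @rdname canned_scripts
#' @export
flight_script <- function(n_frames = 200, onset_frame = 90, latency_frames = 2,
                          flight_speed = 6, direction = c(1, 0.4),
                          arena_size = c(400, 400), framerate = 15) {
  d <- direction / sqrt(sum(direction^2))
  change <- onset_frame + latency_frames
  behaviour_script(data.frame(
    start = c(0, change), end = c(change, n_frames),
    mode = c("still", "flight"),
    vx = c(0, flight_speed * d[1]), vy = c(0, flight_speed * d[2])),
    arena_size = arena_size, framerate = framerate)
}

# Fixed speckled mouse texture: a 2:1 ellipse with high-contrast 2x2-px
# speckle so the Harris detector finds dense corners, as on a real mouse.
mouse_texture <- function(body_length, seed) {
  a <- body_length / 2            # semi-major (x)
  b <- body_length / 4            # semi-minor (y)
  half <- ceiling(a) + 2
  sz <- 2L * half + 1L
  xs <- matrix(rep(-half:half, each = sz), sz, sz)        # x along cols? build grids
  ys <- t(xs)
  mask <- (xs / a)^2 + (ys / b)^2 <= 1
  block <- 2L
  nb <- ceiling(sz / block)
  # high-contrast few-level speckle: strong corner responses at block joints
  vals <- with_seed(seed, matrix(sample(c(90, 150, 210, 255), nb * nb,
                                        replace = TRUE), nb, nb))
  tex <- vals[ceiling(seq_len(sz) / block), ceiling(seq_len(sz) / block)]
  list(tex = tex, mask = mask, half = half, xs = xs, ys = ys, a = a, b = b)
}

#' Render a synthetic open-field trial
#'
#' Renders a textured mouse-like ellipse moving over a static background
#' according to a [behaviour_script()], returning the frames, the clean
#' background frame, and the scripted per-frame body speed as ground truth.
#' The body is a 2:1 ellipse about 8% of the arena width with fixed seeded
#' speckle texture; `head_move` rotates the anterior 40% about the body
#' centre. Mild Gaussian pixel noise (default sd 1 grey level) is added per
#' frame.
#'
#' @param script a `behaviour_script`.
#' @param seed integer seed (texture, pixel noise); fixed seed gives
#'   bit-identical frames.
#' @param start_pos initial body-centre `(x, y)`; default arena centre.
#' @param mouse_length_frac body length as a fraction of arena width.
#' @param pixel_noise_sd per-pixel Gaussian noise, grey levels.
#' @param bounce if `TRUE` (default) the body reflects off the walls,
#'   emulating wall-following; if `FALSE` a script that drives the body out of
#'   bounds is an error.
#' @param head_wobble_deg standard deviation (degrees) of the random per-frame
#'   head-bobbing rotation of the anterior 40% of the body while locomoting;
#'   emulates the heterogeneous part motion of a real mouse (0 disables).
#' @return list with `frames` (list of matrices, grey 0--255), `background`,
#'   and `ground_truth` (data.frame frame/speed/mode/x/y).
#' @export
render_synthetic_trial <- function(script, seed = 1, start_pos = NULL,
                                   mouse_length_frac = 0.1,
                                   pixel_noise_sd = 1, bounce = TRUE,
                                   head_wobble_deg = 2) {
  stopifnot(inherits(script, "behaviour_script"))
  W <- script$arena_size[1]; H <- script$arena_size[2]
  body_length <- mouse_length_frac * W
  tx <- mouse_texture(body_length, seed = child_seed(seed, 1))
  margin <- tx$half + 2
  if (2 * margin >= min(W, H)) stopf("arena too small for the body")
  pos <- start_pos %||% c(W / 2, H / 2)
  if (pos[1] < margin || pos[1] > W - margin || pos[2] < margin || pos[2] > H - margin)
    stopf("start position leaves the body outside the arena")

  # static background: gentle horizontal gradient, darker than the body
  background <- matrix(rep(seq(50, 70, length.out = W), each = H), H, W)

  segs <- script$segments
  n_frames <- script$n_frames
  frames <- vector("list", n_frames)
  gt_speed <- numeric(n_frames)
  gt_mode <- character(n_frames)
  gt_x <- numeric(n_frames); gt_y <- numeric(n_frames)
  angle <- 0   # cumulative anterior rotation (head_move)
  reflect <- function(p, lo, hi) {
    # reflect into [lo, hi]
    span <- hi - lo
    q <- (p - lo) %% (2 * span)
    lo + ifelse(q > span, 2 * span - q, q)
  }
  noise_seed <- child_seed(seed, 2)
  wobble <- if (head_wobble_deg > 0)
    with_seed(child_seed(seed, 3),
              rnorm(n_frames, sd = head_wobble_deg * pi / 180))
  else numeric(n_frames)
  for (f in seq_len(n_frames) - 1L) {
    seg <- segs[segs$start <= f & f < segs$end, ][1, ]
    if (f > 0) {
      prev <- c(gt_x[f], gt_y[f])
      if (seg$mode %in% c("locomote", "flight")) {
        cand <- prev + c(seg$vx, seg$vy)
        if (bounce) {
          cand[1] <- reflect(cand[1], margin, W - margin)
          cand[2] <- reflect(cand[2], margin, H - margin)
        } else if (cand[1] < margin || cand[1] > W - margin ||
                   cand[2] < margin || cand[2] > H - margin) {
          stopf("script drives the body out of bounds at frame %d", f)
        }
        pos <- cand
      }
      if (seg$mode == "head_move") angle <- angle + seg$part_velocity * pi / 180
      gt_speed[f + 1] <- sqrt(sum((pos - prev)^2))
    }
    gt_mode[f + 1] <- seg$mode
    gt_x[f + 1] <- pos[1]; gt_y[f + 1] <- pos[2]
    frame_angle <- angle +
      if (seg$mode %in% c("locomote", "flight")) wobble[f + 1] else 0
    frames[[f + 1]] <- paste_mouse(background, tx, pos, frame_angle)
  }
  if (pixel_noise_sd > 0) {
    frames <- with_seed(noise_seed, lapply(frames, function(fr) {
      fr <- fr + matrix(rnorm(length(fr), sd = pixel_noise_sd),
                        nrow(fr), ncol(fr))
      fr[fr < 0] <- 0
      fr[fr > 255] <- 255
      fr
    }))
  }
  list(frames = frames, background = background,
       ground_truth = data.frame(frame = seq_len(n_frames) - 1L,
                                 speed = gt_speed, mode = gt_mode,
                                 x = gt_x, y = gt_y))
}

# Paste the body texture at integer-rounded centre `pos`; the anterior 40%
# (x > 0.2*a in body frame) is rotated by `angle` about the centre.
paste_mouse <- function(background, tx, pos, angle) {
  fr <- background
  cx <- round(pos[1]); cy <- round(pos[2])
  half <- tx$half
  if (abs(angle) < 1e-12) {
    sel <- which(tx$mask, arr.ind = TRUE)
    rows <- cy + 1L + (sel[, 1] - half - 1L)
    cols <- cx + 1L + (sel[, 2] - half - 1L)
    fr[cbind(rows, cols)] <- tx$tex[sel]
    return(fr)
  }
  # inverse-map each target pixel of the anterior region to the texture
  sel <- which(tx$mask | TRUE, arr.ind = TRUE)  # whole patch
  xs <- sel[, 2] - half - 1L   # body-frame x
  ys <- sel[, 1] - half - 1L
  anterior_cut <- 0.2 * tx$a
  src_x <- xs; src_y <- ys
  ant <- xs > anterior_cut
  ca <- cos(-angle); sa <- sin(-angle)
  src_x[ant] <- round(ca * xs[ant] - sa * ys[ant])
  src_y[ant] <- round(sa * xs[ant] + ca * ys[ant])
  sz <- 2L * half + 1L
  ok <- src_x >= -half & src_x <= half & src_y >= -half & src_y <= half
  src_r <- src_y + half + 1L; src_c <- src_x + half + 1L
  inside <- ok
  inside[ok] <- tx$mask[cbind(src_r[ok], src_c[ok])]
  rows <- cy + 1L + ys[inside]
  cols <- cx + 1L + xs[inside]
  fr[cbind(rows, cols)] <- tx$tex[cbind(src_r[inside], src_c[inside])]
  fr
}
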
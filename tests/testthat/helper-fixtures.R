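# Shared fixture helpers for the test suite. Everything is generated in code;
# small sizes keep the default run fast.

# Matched-pair data.frame from a rigid-motion cloud.
cloud_pairs <- function(cloud) {
  data.frame(x0 = cloud$points_t[, 1], y0 = cloud$points_t[, 2],
             x1 = cloud$points_t1[, 1], y1 = cloud$points_t1[, 2])
}

# A small rendered trial (short, small arena) for tracking unit tests.
small_trial <- function(n_frames = 12, speed = 2, seed = 11,
                        arena = c(400, 400)) {
  sc <- behaviour_script(
    data.frame(start = 0, end = n_frames, mode = "locomote",
               vx = speed, vy = 0),
    arena_size = arena)
  render_synthetic_trial(sc, seed = seed, start_pos = c(60, 200))
}

# Independent quantile oracle: linear interpolation between order statistics
# at h = (n - 1) p + 1, written without stats::quantile.
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Direct evaluation of the description-length formula from a motion model's
# recorded labels/residuals, independent of description_length().
dl_oracle <- function(model, sigma_min = 0.1) {
  N <- length(model$labels)
  K <- model$K
  Lw <- N * log2(K + 1) / log(2)
  Lo <- model$n_outliers * log2(model$bbox_area) / log(2)
  Lm <- 3 / (2 * log(2)) * log2(prod(model$cluster_sizes))
  Lr <- 0
  for (k in seq_len(K)) {
    r <- model$residuals[model$labels == k, , drop = FALSE]
    for (ax in 1:2) {
      v <- r[, ax]
      mu <- mean(v)
      s <- max(sigma_min, sqrt(mean((v - mu)^2)))
      Lr <- Lr + nrow(r) / 2 * log(2 * pi * s^2) + sum((v - mu)^2) / (2 * s^2)
    }
  }
  Lw + Lo + Lm + Lr
}

# Grid-search oracle for the knee: SSE-optimal psi over a fine grid.
knee_grid_oracle <- function(beta, m, grid = NULL) {
  grid <- grid %||% seq(min(beta), max(beta), length.out = 400)
  sse <- vapply(grid, function(psi) {
    U <- pmax(beta - psi, 0)
    sum(stats::resid(stats::lm(m ~ beta + U))^2)
  }, 0)
  grid[which.min(sse)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
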
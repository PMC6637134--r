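test_that("foreground extraction thresholds, opens and bounds", {
  bg <- matrix(100, 60, 60)
  expect_true(compute_foreground(bg, bg)$empty)
  expect_error(compute_foreground(bg, matrix(100, 50, 60)), "shape")

  # a 3x3 blob is removed by opening with a radius-2 disc
  fr <- bg
  fr[20:22, 30:32] <- 200
  expect_true(compute_foreground(fr, bg, opening_radius = 2)$empty)
  # without opening it survives and is tightly boxed
  fg <- compute_foreground(fr, bg, opening_radius = 0)
  expect_false(fg$empty)
  expect_equal(fg$bbox, c(29L, 19L, 32L, 22L))

  # synthetic trial frame: bbox contains >= 95% of true foreground pixels
  tr <- small_trial(n_frames = 3)
  truth <- abs(tr$frames[[2]] - tr$background) > 15
  fg <- compute_foreground(tr$frames[[2]], tr$background)
  idx <- which(truth, arr.ind = TRUE)
  inside <- idx[, 2] - 1 >= fg$bbox[1] & idx[, 2] - 1 < fg$bbox[3] &
            idx[, 1] - 1 >= fg$bbox[2] & idx[, 1] - 1 < fg$bbox[4]
  expect_gte(mean(inside), 0.95)
})

test_that("Harris pyramid detector finds checkerboard corners, none on flat", {
  flat <- matrix(128, 64, 64)
  expect_equal(nrow(detect_landmarks(flat)), 0)

  # 8-px checkerboard: corners at the square intersections
  sq <- 8
  n <- 64
  board <- 255 * outer(0:(n - 1) %/% sq, 0:(n - 1) %/% sq,
                       function(a, b) (a + b) %% 2)
  det <- detect_landmarks(board)
  # interior intersections at (8k - 0.5); detection within 1 px
  grid <- seq(sq, n - sq, by = sq) - 0.5
  hits <- 0
  for (gx in grid) for (gy in grid) {
    d <- sqrt((det$x - gx)^2 + (det$y - gy)^2)
    if (any(d <= 1)) hits <- hits + 1
  }
  expect_gte(hits, 0.8 * length(grid)^2)
  # base-level detections sit on intersections (coarse levels may drift)
  d0 <- det[det$level == 0, ]
  near <- vapply(seq_len(nrow(d0)), function(i)
    min(abs(d0$x[i] - grid)) <= 1 && min(abs(d0$y[i] - grid)) <= 1, TRUE)
  expect_gte(mean(near), 0.9)
})

test_that("mouse frames carry a dense landmark set inside the foreground", {
  tr <- small_trial(n_frames = 3)
  fg <- compute_foreground(tr$frames[[2]], tr$background)
  pad <- 5
  roi <- c(max(0, fg$bbox[1] - pad), max(0, fg$bbox[2] - pad),
           min(ncol(tr$background), fg$bbox[3] + pad),
           min(nrow(tr$background), fg$bbox[4] + pad))
  det <- detect_landmarks(tr$frames[[2]], roi)
  expect_gte(nrow(det), 30)
  # all landmarks inside the mask dilated by 2 px (box check via bbox +- 2)
  expect_true(all(det$x >= fg$bbox[1] - 2 & det$x <= fg$bbox[3] + 2 &
                  det$y >= fg$bbox[2] - 2 & det$y <= fg$bbox[4] + 2))
  # inside the frame
  expect_true(all(det$x >= 0 & det$x < ncol(tr$background) &
                  det$y >= 0 & det$y < nrow(tr$background)))
  expect_error(detect_landmarks(tr$frames[[2]], c(-5, 0, 10, 10)), "roi")
})

test_that("detection is invariant to a uniform intensity offset", {
  tr <- small_trial(n_frames = 3)
  fg <- compute_foreground(tr$frames[[2]], tr$background)
  det1 <- detect_landmarks(tr$frames[[2]], fg$bbox)
  det2 <- detect_landmarks(tr$frames[[2]] + 17, fg$bbox)
  expect_equal(det1$x, det2$x)
  expect_equal(det1$y, det2$y)
})

test_that("matching recovers identity and pure translation", {
  tr <- small_trial(n_frames = 3)
  f <- tr$frames[[2]]
  fg <- compute_foreground(f, tr$background)
  det <- detect_landmarks(f, fg$bbox)
  self <- match_landmarks(det, det, f, f)
  expect_equal(nrow(self), nrow(det))
  expect_true(all(self$correlation > 1 - 1e-9))
  expect_equal(self$x0, self$x1)

  # integer translation of the whole frame
  shift <- function(m, dy, dx) {
    out <- matrix(m[1], nrow(m), ncol(m))
    out[(1 + dy):nrow(m), (1 + dx):ncol(m)] <-
      m[1:(nrow(m) - dy), 1:(ncol(m) - dx)]
    out
  }
  f2 <- shift(f, 2, 3)
  det2 <- det
  det2$x <- det$x + 3
  det2$y <- det$y + 2
  mt <- match_landmarks(det, det2, f, f2)
  expect_gt(nrow(mt), 0.8 * nrow(det))
  expect_true(all(abs(mt$x1 - mt$x0 - 3) < 1e-9))
  expect_true(all(abs(mt$y1 - mt$y0 - 2) < 1e-9))
})

test_that("matching is injective and tracks scripted locomotion speed", {
  tr <- small_trial(n_frames = 6, speed = 2)
  f1 <- tr$frames[[3]]; f2 <- tr$frames[[4]]
  fg1 <- compute_foreground(f1, tr$background)
  fg2 <- compute_foreground(f2, tr$background)
  d1 <- detect_landmarks(f1, fg1$bbox)
  d2 <- detect_landmarks(f2, fg2$bbox)
  mt <- match_landmarks(d1, d2, f1, f2)
  expect_gt(nrow(mt), 10)
  expect_false(any(duplicated(mt[c("x0", "y0")])))
  expect_false(any(duplicated(mt[c("x1", "y1")])))
  disp <- sqrt((mt$x1 - mt$x0)^2 + (mt$y1 - mt$y0)^2)
  expect_lt(abs(median(disp) - 2), 0.5)
})

test_that("centroid tracker follows the scripted path", {
  bg <- matrix(0, 40, 40)
  fr <- bg; fr[21, 11] <- 255
  expect_equal(unname(track_centroid(fr, bg, opening_radius = 0)), c(10, 20))

  # freeze trial: displacement correlates with the scripted speed profile
  sc <- freeze_script(n_frames = 24, onset_frame = 12, latency_frames = 0)
  tr <- render_synthetic_trial(sc, seed = 12, start_pos = c(100, 150))
  cent <- t(vapply(tr$frames, track_centroid, c(x = 0, y = 0),
                   background = tr$background))
  step <- sqrt(diff(cent[, 1])^2 + diff(cent[, 2])^2)
  gt <- tr$ground_truth$speed[-1]
  expect_gte(stats::cor(step, gt), 0.9)
  expect_true(all(is.na(track_centroid(bg, bg))))
})
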
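test_that("RANSAC Procrustes recovers identity and exact translation", {
  cl <- generate_rigid_motion_cloud(
    20, list(list(rotation = 0, translation = c(0, 0), weight = 1)), seed = 1)
  f <- fit_procrustes_ransac(cloud_pairs(cl), seed = 1)
  expect_lt(abs(f$transform$rotation), 1e-9)
  expect_lt(max(abs(f$transform$translation)), 1e-9)
  expect_true(all(f$inliers))
  expect_lt(max(abs(f$residuals)), 1e-9)

  cl <- generate_rigid_motion_cloud(
    20, list(list(rotation = 0, translation = c(3, -2), weight = 1)), seed = 2)
  f <- fit_procrustes_ransac(cloud_pairs(cl), seed = 1)
  expect_lt(abs(f$transform$rotation), 1e-9)
  expect_equal(f$transform$translation, c(3, -2), tolerance = 1e-9)
  expect_true(all(f$inliers))

  expect_error(fit_procrustes_ransac(cloud_pairs(cl)[1, ]), "at least 2")
})

test_that("RANSAC recovers rotation+translation under noise and outliers", {
  errs <- t(vapply(1:25, function(s) {
    cl <- generate_rigid_motion_cloud(
      50, list(list(rotation = 30, translation = c(5, -3), weight = 1)),
      noise_sd = 0.3, outlier_fraction = 0.2, seed = 1000 + s)
    f <- fit_procrustes_ransac(cloud_pairs(cl), seed = s)
    c(rot = abs(f$transform$rotation * 180 / pi - 30),
      trans = max(abs(f$transform$translation - c(5, -3))),
      acc = mean(f$inliers == (cl$labels > 0)))
  }, c(rot = 0, trans = 0, acc = 0)))
  expect_gte(mean(errs[, "rot"] <= 0.5 & errs[, "trans"] <= 0.5 &
                  errs[, "acc"] >= 0.95), 0.95)
})

test_that("refit residual sum does not exceed the minimal-sample model's", {
  set.seed(42)
  for (rep in 1:5) {
    cl <- generate_rigid_motion_cloud(
      30, list(list(rotation = 15, translation = c(2, 1), weight = 1)),
      noise_sd = 0.5, seed = 500 + rep)
    pairs <- cloud_pairs(cl)
    f <- fit_procrustes_ransac(pairs, seed = rep)
    # any exact 2-point model on the same inliers has >= residual sum
    idx <- which(f$inliers)
    p <- cbind(pairs$x0, pairs$y0)[idx, ]
    q <- cbind(pairs$x1, pairs$y1)[idx, ]
    ls_ss <- sum((q - apply_rigid(f$transform, p))^2)
    two <- mousecp:::procrustes_ls(p[1:2, ], q[1:2, ])
    expect_lte(ls_ss, sum((q - apply_rigid(two, p))^2) + 1e-9)
  }
})

test_that("clustered motion with K=1 reduces to the single RANSAC fit", {
  cl <- generate_rigid_motion_cloud(
    30, list(list(rotation = 10, translation = c(2, -1), weight = 1)),
    noise_sd = 0.2, seed = 9)
  pairs <- cloud_pairs(cl)
  single <- fit_procrustes_ransac(pairs, seed = mousecp:::child_seed(3, 7, 1, 1))
  mod <- cluster_motion(pairs, K = 1, seed = 3)
  expect_equal(mod$transforms[[1]]$rotation, single$transform$rotation)
  expect_equal(mod$transforms[[1]]$translation, single$transform$translation)
  expect_equal(mod$labels > 0, single$inliers)
})

test_that("two separated opposite motions are recovered exactly at K=2", {
  cl <- generate_rigid_motion_cloud(
    40, list(list(rotation = 0, translation = c(5, 0), weight = 0.5),
             list(rotation = 0, translation = c(-5, 0), weight = 0.5)),
    seed = 4,
    cluster_boxes = list(c(0, 0, 40, 40), c(60, 60, 100, 100)))
  mod <- cluster_motion(cloud_pairs(cl), K = 2, seed = 5)
  expect_true(mod$feasible)
  # labels recover the groups up to cluster relabelling
  tab <- table(cl$labels, mod$labels)
  expect_equal(sum(apply(tab, 1, max)), 40)
  trans <- sort(vapply(mod$transforms, function(t) t$translation[1], 0))
  expect_equal(trans, c(-5, 5), tolerance = 1e-9)

  # K exceeding what 3 pairs support is infeasible
  expect_false(cluster_motion(cloud_pairs(cl)[1:3, ], K = 2, seed = 1)$feasible)
})

test_that("description length matches independent formula evaluation", {
  # hand-built model: K=1, 10 points, 2 outliers, bbox 100x100
  res <- cbind(c(rep(0.05, 8), 5, -5), c(rep(-0.05, 8), 4, -4))
  model <- structure(list(
    K = 1L, transforms = list(rigid_transform()),
    labels = c(rep(1L, 8), 0L, 0L), residuals = res,
    cluster_sizes = 8L, n_outliers = 2L, bbox_area = 100 * 100,
    feasible = TRUE), class = "motion_model")
  dl <- description_length(model)
  expect_equal(dl$L_outlier, 2 * log2(10000) / log(2))
  expect_equal(dl$L_which_model, 10 * log2(2) / log(2))
  expect_equal(dl$L_model, 3 / (2 * log(2)) * log2(8))
  expect_equal(dl$DL,
               dl$L_which_model + dl$L_outlier + dl$L_model + dl$L_residuals)
  expect_equal(dl$DL, dl_oracle(model))

  # with MLE sigma above the floor, each axis residual sum term equals N_i/2
  res2 <- cbind(rnorm(20, sd = 2), rnorm(20, sd = 2))
  m2 <- structure(list(K = 1L, transforms = list(rigid_transform()),
                       labels = rep(1L, 20), residuals = res2,
                       cluster_sizes = 20L, n_outliers = 0L,
                       bbox_area = 1e4, feasible = TRUE),
                  class = "motion_model")
  d2 <- description_length(m2)
  gauss <- 20 / 2 * (log(2 * pi * mean((res2[, 1] - mean(res2[, 1]))^2)) +
                     log(2 * pi * mean((res2[, 2] - mean(res2[, 2]))^2)))
  expect_equal(d2$L_residuals - gauss, 20, tolerance = 1e-9)
  expect_equal(d2$L_outlier, 0)
})

test_that("DL is invariant to translating all points", {
  cl <- generate_rigid_motion_cloud(
    30, list(list(rotation = 5, translation = c(1, 2), weight = 1)),
    noise_sd = 0.3, seed = 8)
  pairs <- cloud_pairs(cl)
  m1 <- cluster_motion(pairs, K = 1, seed = 2, bbox_area = 1e4)
  shifted <- pairs
  shifted[c("x0", "x1")] <- shifted[c("x0", "x1")] + 100
  shifted[c("y0", "y1")] <- shifted[c("y0", "y1")] + 50
  m2 <- cluster_motion(shifted, K = 1, seed = 2, bbox_area = 1e4)
  expect_equal(description_length(m1)$DL, description_length(m2)$DL,
               tolerance = 1e-9)
})

test_that("MDL selects the true number of motion clusters", {
  # compact, well-separated patches so coordinate clustering can recover them
  boxes3 <- list(c(0, 0, 30, 30), c(70, 0, 100, 30), c(35, 70, 65, 100))
  spec_for <- function(K) {
    trans <- list(c(0, 0), c(6, 0), c(0, -6))[1:K]
    list(clusters = lapply(trans, function(tt)
      list(rotation = 0, translation = tt, weight = 1 / K)),
      boxes = boxes3[1:K])
  }
  for (K_true in 1:3) {
    sp <- spec_for(K_true)
    hits <- vapply(1:20, function(s) {
      cl <- generate_rigid_motion_cloud(60, sp$clusters, noise_sd = 0.3,
                                        seed = 3000 + 100 * K_true + s,
                                        cluster_boxes = sp$boxes)
      mod <- select_motion_model(cloud_pairs(cl), seed = s, bbox_area = 1e4)
      mod$K == K_true
    }, TRUE)
    expect_gte(mean(hits), 0.9)
  }
})

test_that("selected model's DL equals re-evaluation and beats other K", {
  cl <- generate_rigid_motion_cloud(
    60, list(list(rotation = 0, translation = c(4, 0), weight = 0.5),
             list(rotation = 0, translation = c(-4, 0), weight = 0.5)),
    noise_sd = 0.3, seed = 77,
    cluster_boxes = list(c(0, 0, 45, 45), c(55, 55, 100, 100)))
  mod <- select_motion_model(cloud_pairs(cl), seed = 6, bbox_area = 1e4)
  expect_equal(mod$dl$DL, dl_oracle(mod), tolerance = 1e-9)
  expect_equal(min(mod$dl_by_K, na.rm = TRUE), mod$dl$DL)
})
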
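#' Rigid 2-D transform (rotation + translation, no scaling)
#'
#' The partial Procrustes superimposition between two point sets: a rotation
#' in `(-pi, pi]` followed by a translation. Three free parameters (one for
#' rotation, two for translation).
#'
#' @param rotation angle in radians.
#' @param translation length-2 px vector.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = 0, translation = c(0, 0)) {
  rotation <- atan2(sin(rotation), cos(rotation))   # wrap to (-pi, pi]
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to an n x 2 point matrix
#' @param tf a [rigid_transform()].
#' @param pts n x 2 matrix of `(x, y)` points.
#' @return transformed n x 2 matrix.
#' @export
apply_rigid <- function(tf, pts) {
  ca <- cos(tf$rotation); sa <- sin(tf$rotation)
  cbind(ca * pts[, 1] - sa * pts[, 2] + tf$translation[1],
        sa * pts[, 1] + ca * pts[, 2] + tf$translation[2])
}

# Least-squares rotation+translation aligning p -> q (2-D orthogonal
# Procrustes without scaling, via the cross/dot sums of centred coordinates).
procrustes_ls <- function(p, q) {
  pc <- sweep(p, 2, colMeans(p))
  qc <- sweep(q, 2, colMeans(q))
  num <- sum(pc[, 1] * qc[, 2] - pc[, 2] * qc[, 1])
  den <- sum(pc[, 1] * qc[, 1] + pc[, 2] * qc[, 2])
  theta <- if (num == 0 && den == 0) 0 else atan2(num, den)
  ca <- cos(theta); sa <- sin(theta)
  mp <- colMeans(p); mq <- colMeans(q)
  tr <- c(mq[1] - (ca * mp[1] - sa * mp[2]), mq[2] - (sa * mp[1] + ca * mp[2]))
  rigid_transform(theta, tr)
}

pairs_to_mats <- function(pairs) {
  list(p = cbind(pairs$x0, pairs$y0), q = cbind(pairs$x1, pairs$y1))
}

#' Robust partial Procrustes fit with RANSAC
#'
#' Estimates a single rotation+translation between matched landmark pairs,
#' rejecting outliers: minimal samples of two pairs exactly determine a
#' candidate transform; the consensus-maximal candidate (pairs with residual
#' below `inlier_threshold`) is refitted by least squares on its inliers and
#' inlier flags are recomputed on the refit.
#'
#' @param pairs data.frame of matches (`x0`, `y0`, `x1`, `y1`), e.g. from
#'   [match_landmarks()].
#' @param inlier_threshold residual radius (px) counting a pair as inlier.
#' @param n_iterations number of minimal samples.
#' @param seed optional integer seed.
#' @return list with `transform` ([rigid_transform()]), `inliers` (logical),
#'   `residuals` (n x 2 matrix, signed per-axis) and `n_inliers`.
#' @export
fit_procrustes_ransac <- function(pairs, inlier_threshold = 10,
                                  n_iterations = 200, seed = NULL) {
  n <- nrow(pairs)
  if (n < 2) stopf("need at least 2 matched pairs")
  m <- pairs_to_mats(pairs)
  p <- m$p; q <- m$q
  with_seed(seed, {
    i1 <- sample.int(n, n_iterations, replace = TRUE)
    i2 <- sample.int(n, n_iterations, replace = TRUE)
    sep <- (p[i1, 1] - p[i2, 1])^2 + (p[i1, 2] - p[i2, 2])^2 > 1e-12
    i1 <- i1[sep]; i2 <- i2[sep]
    if (length(i1) == 0) stopf("all RANSAC samples degenerate (coincident points)")
    dpx <- p[i2, 1] - p[i1, 1]; dpy <- p[i2, 2] - p[i1, 2]
    dqx <- q[i2, 1] - q[i1, 1]; dqy <- q[i2, 2] - q[i1, 2]
    theta <- atan2(dpx * dqy - dpy * dqx, dpx * dqx + dpy * dqy)
    ca <- cos(theta); sa <- sin(theta)
    # translation from the sample midpoint
    mpx <- (p[i1, 1] + p[i2, 1]) / 2; mpy <- (p[i1, 2] + p[i2, 2]) / 2
    mqx <- (q[i1, 1] + q[i2, 1]) / 2; mqy <- (q[i1, 2] + q[i2, 2]) / 2
    tx <- mqx - (ca * mpx - sa * mpy)
    ty <- mqy - (sa * mpx + ca * mpy)
    # residuals of all n pairs under every candidate (iters x n)
    prx <- outer(ca, p[, 1]) - outer(sa, p[, 2]) + tx
    pry <- outer(sa, p[, 1]) + outer(ca, p[, 2]) + ty
    r2 <- (prx - rep(q[, 1], each = length(theta)))^2 +
          (pry - rep(q[, 2], each = length(theta)))^2
    dim(r2) <- c(length(theta), n)
    inl <- r2 <= inlier_threshold^2
    counts <- rowSums(inl)
    best_count <- max(counts)
    cand <- which(counts == best_count)
    if (length(cand) > 1) {
      ssr <- rowSums(r2[cand, , drop = FALSE] * inl[cand, , drop = FALSE])
      cand <- cand[which.min(ssr)]
    } else cand <- cand[1]
    flags <- inl[cand, ]
    if (sum(flags) < 2) flags <- rep(TRUE, n)  # fall back to all pairs
    tf <- procrustes_ls(p[flags, , drop = FALSE], q[flags, , drop = FALSE])
    pred <- apply_rigid(tf, p)
    res <- q - pred
    flags <- res[, 1]^2 + res[, 2]^2 <= inlier_threshold^2
    if (sum(flags) >= 2) {
      tf <- procrustes_ls(p[flags, , drop = FALSE], q[flags, , drop = FALSE])
      pred <- apply_rigid(tf, p)
      res <- q - pred
      flags <- res[, 1]^2 + res[, 2]^2 <= inlier_threshold^2
    }
    list(transform = tf, inliers = flags, residuals = res,
         n_inliers = sum(flags))
  })
}

# k-means++ seeding (Arthur & Vassilvitskii) on the rows of X.
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(NA_real_, K, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  if (K > 1) for (k in 2:K) {
    if (sum(d2) <= 0) {
      centers[k, ] <- X[sample.int(n, 1), ]
    } else {
      centers[k, ] <- X[sample.int(n, 1, prob = d2), ]
    }
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[k, ])^2))
  }
  centers
}

#' Clustered rigid-motion model for one frame pair
#'
#' Clusters the previous-frame landmark coordinates with k-means++ (best of
#' `n_restarts` by within-cluster sum of squares), then fits a RANSAC partial
#' Procrustes transform separately to each cluster. RANSAC outliers of all
#' clusters are pooled.
#'
#' @inheritParams fit_procrustes_ransac
#' @param K number of clusters (>= 1).
#' @param n_restarts k-means++ restarts.
#' @param bbox_area area (px^2) of the animal bounding box, used later by
#'   [description_length()]; defaults to the bounding-box area of the
#'   previous-frame landmarks.
#' @param ransac_iterations minimal samples per cluster fit.
#' @return object of class `motion_model`: `K`, `transforms`, `labels`
#'   (per-pair cluster id, 0 = outlier), `residuals` (n x 2), `cluster_sizes`
#'   (inliers per cluster), `n_outliers`, `bbox_area`, `feasible`.
#' @export
cluster_motion <- function(pairs, K, n_restarts = 10, inlier_threshold = 10,
                           seed = NULL, bbox_area = NULL,
                           ransac_iterations = 200) {
  n <- nrow(pairs)
  infeasible <- structure(list(K = K, feasible = FALSE), class = "motion_model")
  if (K < 1) stopf("K must be >= 1")
  if (n < 2 * K) return(infeasible)
  m <- pairs_to_mats(pairs)
  if (is.null(bbox_area)) {
    bbox_area <- max(1, diff(range(m$p[, 1])) * diff(range(m$p[, 2])))
  }
  assign_best <- NULL
  if (K == 1) {
    assign_best <- rep(1L, n)
  } else {
    best_wcss <- Inf
    with_seed(child_seed(seed, K), for (r in seq_len(n_restarts)) {
      centers <- kmeanspp_centers(m$p, K)
      cl <- if (anyDuplicated(centers)) NULL else
        tryCatch(suppressWarnings(
          kmeans(m$p, centers = centers, iter.max = 50, algorithm = "Lloyd")),
          error = function(e) NULL)
      if (is.null(cl)) next
      if (min(tabulate(cl$cluster, K)) < 2) next
      if (cl$tot.withinss < best_wcss) {
        best_wcss <- cl$tot.withinss
        assign_best <- cl$cluster
      }
    })
    if (is.null(assign_best)) return(infeasible)
  }
  transforms <- vector("list", K)
  labels <- integer(n)
  residuals <- matrix(NA_real_, n, 2)
  for (k in seq_len(K)) {
    idx <- which(assign_best == k)
    fit <- fit_procrustes_ransac(pairs[idx, , drop = FALSE],
                                 inlier_threshold = inlier_threshold,
                                 n_iterations = ransac_iterations,
                                 seed = child_seed(seed, 7, K, k))
    transforms[[k]] <- fit$transform
    labels[idx] <- ifelse(fit$inliers, k, 0L)
    residuals[idx, ] <- fit$residuals
  }
  sizes <- tabulate(labels[labels > 0], K)
  structure(list(K = K, transforms = transforms, labels = labels,
                 residuals = residuals, cluster_sizes = sizes,
                 n_outliers = sum(labels == 0), bbox_area = bbox_area,
                 feasible = all(sizes >= 1)),
            class = "motion_model")
}

#' Description length of a clustered motion model
#'
#' Computes the minimum-description-length score used to select the number of
#' motion clusters. With `N` landmark pairs, `K` clusters of `N_i` inliers,
#' `N_outlier` outliers, and an animal bounding box of area `Nx*Ny`:
#'
#' \deqn{L_{which\_model} = N \log_2(K+1)/\ln 2}
#' \deqn{L_{outlier} = N_{outlier} \log_2(N_x N_y)/\ln 2}
#' \deqn{L_{model} = \frac{3}{2\ln 2} \log_2 \prod_i N_i}
#' \deqn{L_{residuals} = \sum_i \frac{N_i}{2}[\ln(2\pi\sigma_{x_i}^2) +
#'   \ln(2\pi\sigma_{y_i}^2)] + \sum_j \frac{(x_{ij}-\mu_{x_i})^2}
#'   {2\sigma_{x_i}^2} + \sum_j \frac{(y_{ij}-\mu_{y_i})^2}{2\sigma_{y_i}^2}}
#'
#' where the residual code length is the Gaussian negative log likelihood
#' with per-cluster per-axis mean and maximum-likelihood standard deviation
#' (floored at `sigma_min` to stay finite on noise-free data), the model cost
#' charges the 3 parameters of each rotation+translation, and outliers are
#' coded as bounded integers in the box. The double conversion
#' `log2(.)/ln 2` is evaluated exactly as written.
#'
#' @param model a feasible `motion_model` from [cluster_motion()].
#' @param sigma_min lower bound on the residual standard deviations, px.
#' @return object of class `description_length` with components
#'   `L_which_model`, `L_outlier`, `L_model`, `L_residuals` and total `DL`.
#' @export
description_length <- function(model, sigma_min = 0.1) {
  stopifnot(inherits(model, "motion_model"))
  if (!isTRUE(model$feasible)) stopf("model is infeasible")
  if (any(model$cluster_sizes == 0)) stopf("empty cluster")
  if (model$bbox_area <= 0) stopf("bbox_area must be positive")
  N <- length(model$labels)
  K <- model$K
  Lw <- N * log2(K + 1) / log(2)
  Lo <- model$n_outliers * log2(model$bbox_area) / log(2)
  Lm <- 3 / (2 * log(2)) * log2(prod(model$cluster_sizes))
  Lr <- 0
  for (k in seq_len(K)) {
    idx <- which(model$labels == k)
    rx <- model$residuals[idx, 1]; ry <- model$residuals[idx, 2]
    Ni <- length(idx)
    mux <- mean(rx); muy <- mean(ry)
    sx <- max(sigma_min, sqrt(mean((rx - mux)^2)))
    sy <- max(sigma_min, sqrt(mean((ry - muy)^2)))
    Lr <- Lr + Ni / 2 * (log(2 * pi * sx^2) + log(2 * pi * sy^2)) +
      sum((rx - mux)^2) / (2 * sx^2) + sum((ry - muy)^2) / (2 * sy^2)
  }
  structure(list(L_which_model = Lw, L_outlier = Lo, L_model = Lm,
                 L_residuals = Lr, DL = Lw + Lo + Lm + Lr),
            class = "description_length")
}

#' Select the number of motion clusters by minimum description length
#'
#' Fits [cluster_motion()] for each K in `K_range` and returns the feasible
#' model with the smallest [description_length()], ties broken toward the
#' smaller K.
#'
#' @inheritParams cluster_motion
#' @param K_range candidate cluster counts (default 1..5).
#' @param sigma_min passed to [description_length()].
#' @return the selected `motion_model`, with its `description_length` attached
#'   as `$dl` and all candidate DLs as `$dl_by_K`.
#' @export
select_motion_model <- function(pairs, K_range = 1:5, n_restarts = 10,
                                inlier_threshold = 10, seed = NULL,
                                bbox_area = NULL, ransac_iterations = 200,
                                sigma_min = 0.1) {
  best <- NULL
  dls <- rep(NA_real_, length(K_range))
  for (i in seq_along(K_range)) {
    mod <- cluster_motion(pairs, K_range[i], n_restarts = n_restarts,
                          inlier_threshold = inlier_threshold, seed = seed,
                          bbox_area = bbox_area,
                          ransac_iterations = ransac_iterations)
    if (!isTRUE(mod$feasible)) next
    dl <- description_length(mod, sigma_min = sigma_min)
    dls[i] <- dl$DL
    if (is.null(best) || dl$DL < best$dl$DL - 1e-12) {
      mod$dl <- dl
      best <- mod
    }
  }
  if (is.null(best)) stopf("no feasible number of clusters in K_range")
  best$dl_by_K <- stats::setNames(dls, K_range)
  best
}
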
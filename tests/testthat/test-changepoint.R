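test_that("segment cost equals the naive two-pass computation", {
  expect_equal(segment_cost(rep(4, 10), 0, 9), 0)
  expect_equal(segment_cost(c(0, 10), 0, 1), 50)
  set.seed(5)
  y <- rnorm(40)
  for (rep in 1:20) {
    ij <- sort(sample(0:39, 2))
    seg <- y[(ij[1] + 1):(ij[2] + 1)]
    expect_equal(segment_cost(y, ij[1], ij[2]),
                 sum((seg - mean(seg))^2), tolerance = 1e-9)
  }
  expect_error(segment_cost(y, 5, 2), "i must be")
})

test_that("PELT handles flat and perfect-step series", {
  flat <- pelt_segment(rep(2, 30), beta = 1)
  expect_length(flat$changepoints, 0)
  expect_equal(flat$total_cost, 0)

  step <- pelt_segment(c(0, 0, 0, 10, 10, 10), beta = 0.1)
  expect_identical(step$changepoints, 2L)
  expect_equal(step$total_cost, 0.1)

  expect_error(pelt_segment(c(1, NA, 3), 1), "finite")
  expect_error(pelt_segment(c(1, 2, 3), 1, min_seg = 2), "shorter")
})

test_that("PELT equals the exhaustive oracle on random series", {
  set.seed(20)
  for (i in 1:60) {
    k <- sample(1:3, 1)
    n <- sample(6:14, 1)
    lens <- diff(c(0, sort(sample(seq_len(n - 1), k - 1)), n))
    if (any(lens < 1)) next
    g <- generate_piecewise_series(stats::rnorm(k, sd = 3), lens,
                                   noise_sd = 1, seed = 2000 + i)
    for (b in c(0.5, 1, 5)) {
      a <- pelt_segment(g$series, b)
      e <- exhaustive_segment(g$series, b)
      expect_identical(a$changepoints, e$changepoints)
      expect_equal(a$total_cost, e$total_cost, tolerance = 1e-9)
    }
  }
})

test_that("stored cost re-evaluates from the changepoints", {
  set.seed(21)
  y <- generate_piecewise_series(c(0, 4, 1), c(30, 30, 30), noise_sd = 1,
                                 seed = 9)$series
  s <- pelt_segment(y, beta = 2)
  bounds <- c(-1, s$changepoints, length(y) - 1)
  cost <- sum(vapply(seq_len(length(bounds) - 1), function(i)
    segment_cost(y, bounds[i] + 1, bounds[i + 1]), 0)) + 2 * s$m
  expect_equal(s$total_cost, cost, tolerance = 1e-9)
})

test_that("PELT is shift invariant and scale covariant", {
  y <- generate_piecewise_series(c(0, 5), c(25, 25), noise_sd = 1,
                                 seed = 31)$series
  s1 <- pelt_segment(y, 3)
  expect_identical(pelt_segment(y + 100, 3)$changepoints, s1$changepoints)
  s2 <- pelt_segment(2 * y, 4 * 3)
  expect_identical(s2$changepoints, s1$changepoints)
  expect_equal(s2$total_cost, 4 * s1$total_cost, tolerance = 1e-6)
})

test_that("zero penalty splits everywhere; exhaustive refuses big n", {
  y <- c(1, 5, 2, 8, 3, 9)
  e <- exhaustive_segment(y, beta = 0)
  expect_identical(e$changepoints, 0:4)
  expect_error(exhaustive_segment(rnorm(30), 1), "refused")
})

test_that("CROPS covers the penalty range consistently with grid PELT", {
  g <- generate_piecewise_series(c(0, 6, 2), c(15, 20, 15), noise_sd = 1,
                                 seed = 41)
  path <- crops_path(g$series, 0.1, 100)
  iv <- path$intervals
  # coverage without overlap, m non-increasing
  expect_equal(iv$beta_low[1], 0.1)
  expect_equal(iv$beta_high[nrow(iv)], 100)
  if (nrow(iv) > 1) {
    expect_equal(iv$beta_low[-1], iv$beta_high[-nrow(iv)], tolerance = 1e-12)
    expect_true(all(diff(iv$m) <= 0))
  }
  for (b in seq(0.1, 100, length.out = 60)) {
    direct <- pelt_segment(g$series, b)
    via <- path_segmentation(path, b)
    expect_equal(direct$m, via$m)
    expect_equal(direct$total_cost,
                 via$total_cost - via$beta * via$m + b * via$m,
                 tolerance = 1e-9)
  }
})

test_that("CROPS transition for a clean step sits at the cost difference", {
  y <- c(rep(0, 10), rep(10, 10))
  path <- crops_path(y, 0.01, 1000)
  iv <- path$intervals
  expect_true(any(iv$m == 1) && any(iv$m == 0))
  # unpenalised cost of no-change model is 20 * 25 = 500; with change, 0
  trans <- iv$beta_high[iv$m == 1][sum(iv$m == 1)]
  expect_equal(trans, 500, tolerance = 1e-9)
  flat <- crops_path(rep(1, 20), 0.1, 10)
  expect_equal(nrow(flat$intervals), 1)
  expect_equal(flat$intervals$m, 0)
})

test_that("knee fit recovers exact two-line parameters and flags lines", {
  beta <- seq(0, 10, length.out = 50)
  m <- -2 * beta + 1.9 * pmax(beta - 5, 0) + 40
  k <- fit_knee(data.frame(beta = beta, m = m))
  expect_true(k$converged)
  expect_equal(k$psi, 5, tolerance = 1e-6)
  expect_equal(k$a, -2, tolerance = 1e-6)
  expect_equal(k$b, 1.9, tolerance = 1e-5)
  expect_equal(k$c, 40, tolerance = 1e-5)

  line <- fit_knee(data.frame(beta = beta, m = 3 - 0.5 * beta))
  expect_true(line$degenerate)
  expect_error(fit_knee(data.frame(beta = c(1, 1, 2), m = c(1, 1, 0))),
               "4 distinct")
})

test_that("knee estimates on noisy data agree with a grid-search oracle", {
  # steep over-fitting branch, shallow under-fitting branch: the shape of
  # changepoint-count-versus-penalty curves
  errs <- psis <- numeric(30)
  for (s in 1:30) {
    beta <- seq(0, 10, length.out = 50)
    m <- -8 * beta + 7.7 * pmax(beta - 5, 0) + 60 +
      mousecp:::with_seed(600 + s, rnorm(50, sd = 2))
    k <- fit_knee(data.frame(beta = beta, m = m))
    psis[s] <- k$psi
    errs[s] <- abs(k$psi - knee_grid_oracle(beta, m,
                                            grid = seq(2, 8, by = 0.01)))
  }
  expect_lte(median(abs(psis - 5)), 0.25)
  expect_gte(mean(abs(psis - 5) <= 1), 0.9)
  expect_lte(median(errs), 0.1)
})

test_that("penalty choice is the median knee, robust to outliers", {
  expect_equal(choose_penalty(5), 5)
  expect_equal(choose_penalty(c(2, 4, 9)), 4)
  expect_equal(choose_penalty(c(3, 3, 3, 3, 50)), 3)
  expect_error(choose_penalty(numeric()), "no converged")
})

test_that("pooled changepoints count channels per frame and conserve totals", {
  none <- pool_changepoints(list(pelt_segment(rep(1, 20), 1)), 20)
  expect_equal(unclass(none), rep(0L, 20))

  segs <- lapply(1:10, function(i)
    mousecp:::new_segmentation(90L, 0, 1, 200))
  p <- pool_changepoints(segs, 200)
  expect_equal(unclass(p)[91], 10L)
  expect_equal(sum(unclass(p)), 10L)
  expect_error(pool_changepoints(
    list(mousecp:::new_segmentation(250L, 0, 1, 300)), 200), "outside")
})
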
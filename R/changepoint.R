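#' Squared-error cost of one segment
#'
#' The within-segment sum of squared deviations from the segment mean,
#' `sum((y[i..j] - mean(y[i..j]))^2)` — the cost assigned to a segment whose
#' model is its average speed.
#'
#' @param series numeric vector.
#' @param i,j segment bounds, 0-based inclusive, `i <= j`.
#' @return non-negative scalar.
#' @export
segment_cost <- function(series, i, j) {
  n <- length(series)
  if (i > j) stopf("i must be <= j")
  if (i < 0 || j >= n) stopf("segment outside series")
  y <- series[(i + 1):(j + 1)]
  sum((y - mean(y))^2)
}

# Prefix-sum machinery: cost of 1-based segment (a..b) in O(1).
make_costfun <- function(series) {
  s1 <- c(0, cumsum(series))
  s2 <- c(0, cumsum(series^2))
  function(a, b) {
    len <- b - a + 1
    cost <- s2[b + 1] - s2[a] - (s1[b + 1] - s1[a])^2 / len
    pmax(cost, 0)
  }
}

new_segmentation <- function(changepoints, total_cost, beta, n) {
  structure(list(changepoints = as.integer(changepoints),
                 m = length(changepoints),
                 total_cost = total_cost, beta = beta, n = as.integer(n)),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("segmentation: n=%d, beta=%g, m=%d changepoints [%s], cost=%g\n",
              x$n, x$beta, x$m, paste(x$changepoints, collapse = ", "),
              x$total_cost))
  invisible(x)
}

#' Exact penalised segmentation with PELT
#'
#' Minimises the penalised cost
#' `sum_i C(y[tau[i-1]+1 .. tau[i]]) + beta * m` over all segmentations,
#' where `C` is the squared-error cost ([segment_cost()]), `m` the number of
#' changepoints and `beta` the per-changepoint penalty, using the pruned
#' exact dynamic programme: candidate split points are discarded as soon as
#' they can no longer participate in an optimum (pruning constant 0 for this
#' cost), giving the exact global optimum in near-linear expected time.
#'
#' @param series numeric vector (finite values).
#' @param beta penalty per changepoint, >= 0.
#' @param min_seg minimum segment length (default 1).
#' @return object of class `segmentation`: `changepoints` (0-based last index
#'   of each non-final segment), `m`, `total_cost` (penalised objective),
#'   `beta`, `n`.
#' @export
pelt_segment <- function(series, beta, min_seg = 1) {
  n <- length(series)
  if (!all(is.finite(series))) stopf("series contains non-finite values")
  if (beta < 0) stopf("beta must be >= 0")
  if (n < 2 * min_seg) stopf("series shorter than two minimum segments")
  C <- make_costfun(series)
  F <- rep(Inf, n + 1)
  F[1] <- -beta
  prev <- integer(n + 1)
  cand <- 0L                           # candidate last-indices s (1-based, 0 = none)
  for (t in seq_len(n)) {
    ok <- cand <= t - min_seg
    if (!any(ok)) next
    s <- cand[ok]
    vals <- F[s + 1] + C(s + 1, t) + beta
    best <- which.min(vals)
    F[t + 1] <- vals[best]
    prev[t + 1] <- s[best]
    keep <- rep(TRUE, length(cand))
    keep[ok] <- vals - beta <= F[t + 1] + 1e-9
    cand <- c(cand[keep], t)
  }
  cps <- integer(0)
  t <- n
  while (t > 0) {
    s <- prev[t + 1]
    if (s > 0) cps <- c(s, cps)
    t <- s
  }
  new_segmentation(cps - 1L, F[n + 1], beta, n)
}

#' Exhaustive-enumeration segmentation oracle
#'
#' Enumerates every admissible changepoint subset and returns the minimiser
#' of the same penalised objective as [pelt_segment()]. Exponential in `n`;
#' refuses `n > 25`. Ties are broken by fewer changepoints, then
#' lexicographically smallest changepoint set. Intended as an independent
#' optimality check for the pruned dynamic programme.
#'
#' @inheritParams pelt_segment
#' @return a `segmentation`.
#' @export
exhaustive_segment <- function(series, beta, min_seg = 1) {
  n <- length(series)
  if (n > 25) stopf("exhaustive enumeration refused for n > 25")
  if (!all(is.finite(series))) stopf("series contains non-finite values")
  if (n < 2 * min_seg) stopf("series shorter than two minimum segments")
  C <- make_costfun(series)
  seg_total <- function(cps) {            # cps: 1-based last indices
    b <- c(cps, n)
    a <- c(1, cps + 1)
    sum(C(a, b)) + beta * length(cps)
  }
  positions <- seq_len(n - 1)
  positions <- positions[positions >= min_seg & positions <= n - min_seg]
  best_cost <- seg_total(integer(0))
  best_cps <- integer(0)
  if (length(positions) > 0) {
    for (k in seq_len(length(positions))) {
      combos <- combn(positions, k)
      for (ci in seq_len(ncol(combos))) {
        cps <- combos[, ci]
        if (k > 1 && any(diff(cps) < min_seg)) next
        cost <- seg_total(cps)
        if (cost < best_cost - 1e-9) {
          best_cost <- cost
          best_cps <- cps
        }
      }
    }
  }
  new_segmentation(best_cps - 1L, best_cost, beta, n)
}

#' CROPS: all optimal segmentations over a penalty interval
#'
#' Enumerates every segmentation that is optimal for some penalty
#' `beta` in `[beta_min, beta_max]`. The interval is subdivided recursively:
#' with `m(b0) > m(b1) + 1`, the candidate crossing penalty
#' `b* = (Q(b1) - Q(b0)) / (m(b0) - m(b1))` (Q = unpenalised cost) is probed
#' with [pelt_segment()] and recursion continues until every sub-interval is
#' resolved, guaranteeing that for every penalty in range the optimal
#' segmentation is the one attached to the covering interval.
#'
#' @inheritParams pelt_segment
#' @param beta_min,beta_max penalty range, `0 <= beta_min < beta_max`.
#' @return object of class `penalty_path`: `intervals` (data.frame
#'   `beta_low`, `beta_high`, `m`), `segmentations` (list, one per interval),
#'   `beta_range`, `n_pelt_runs`.
#' @export
crops_path <- function(series, beta_min, beta_max, min_seg = 1) {
  if (!(beta_min >= 0 && beta_min < beta_max)) stopf("invalid penalty range")
  runs <- 0L
  solve <- function(b) {
    runs <<- runs + 1L
    pelt_segment(series, b, min_seg)
  }
  unpen <- function(s) s$total_cost - s$beta * s$m
  rec <- function(b0, b1, s0, s1) {
    if (s0$m == s1$m) {
      return(list(list(beta_low = b0, beta_high = b1, seg = s0)))
    }
    bstar <- (unpen(s1) - unpen(s0)) / (s0$m - s1$m)
    bstar <- min(max(bstar, b0), b1)
    if (s0$m == s1$m + 1 || bstar <= b0 || bstar >= b1) {
      return(list(list(beta_low = b0, beta_high = bstar, seg = s0),
                  list(beta_low = bstar, beta_high = b1, seg = s1)))
    }
    sstar <- solve(bstar)
    if (sstar$m == s1$m) {
      return(list(list(beta_low = b0, beta_high = bstar, seg = s0),
                  list(beta_low = bstar, beta_high = b1, seg = s1)))
    }
    c(rec(b0, bstar, s0, sstar), rec(bstar, b1, sstar, s1))
  }
  s0 <- solve(beta_min)
  s1 <- solve(beta_max)
  iv <- rec(beta_min, beta_max, s0, s1)
  iv <- iv[vapply(iv, function(x) x$beta_high > x$beta_low, TRUE)]
  intervals <- data.frame(
    beta_low = vapply(iv, `[[`, 0, "beta_low"),
    beta_high = vapply(iv, `[[`, 0, "beta_high"),
    m = vapply(iv, function(x) x$seg$m, 0L))
  ord <- order(intervals$beta_low)
  structure(list(intervals = intervals[ord, , drop = FALSE],
                 segmentations = lapply(iv, `[[`, "seg")[ord],
                 beta_range = c(beta_min, beta_max),
                 n_pelt_runs = runs),
            class = "penalty_path")
}

#' Look up the optimal segmentation for a penalty on a CROPS path
#' @param path a `penalty_path`.
#' @param beta penalty within the path's range.
#' @return the covering interval's `segmentation`.
#' @export
path_segmentation <- function(path, beta) {
  iv <- path$intervals
  if (beta < path$beta_range[1] || beta > path$beta_range[2])
    stopf("beta outside the path's range")
  i <- which(iv$beta_low <= beta & beta <= iv$beta_high)[1]
  path$segmentations[[i]]
}

#' Support points of a penalty path for knee fitting
#'
#' One `(beta, m)` point per interval boundary plus interval midpoints,
#' deduplicated (a boundary belongs to the lower interval).
#'
#' @param path a `penalty_path`.
#' @return data.frame with columns `beta`, `m`.
#' @export
path_support <- function(path) {
  iv <- path$intervals
  beta <- c(iv$beta_low, (iv$beta_low + iv$beta_high) / 2,
            iv$beta_high[nrow(iv)])
  m <- c(iv$m, iv$m, iv$m[nrow(iv)])
  ord <- order(beta)
  beta <- beta[ord]; m <- m[ord]
  keep <- !duplicated(round(beta, 12))
  data.frame(beta = beta[keep], m = m[keep])
}

#' Fit the penalty-selection knee by segmented regression
#'
#' Models the number of changepoints as a function of the penalty as two
#' straight lines meeting at a breakpoint ("knee"):
#' `E[m] = a*beta + b*(beta - psi)_+ + c`, with `a` the left-hand slope, `b`
#' the difference between right and left slopes and `psi` the knee. The knee
#' marks the transition between over- and under-fitting, so it is the
#' natural penalty choice. Parameters are estimated by Muggeo's iterative
#' linearisation: given the current `psi`, regress on `beta`,
#' `(beta - psi)_+` and the indicator `-1(beta > psi)`, then update `psi` by
#' the ratio of the indicator and slope-difference coefficients, to
#' convergence.
#'
#' @param support data.frame with columns `beta`, `m` (e.g. from
#'   [path_support()]), or a `penalty_path`.
#' @param psi0 initial knee; default the median support penalty.
#' @param tol convergence tolerance on `psi`.
#' @param max_iter maximum iterations.
#' @return object of class `knee_fit`: `a`, `b`, `c`, `psi`, `converged`,
#'   `degenerate`, `iterations`, `sse`.
#' @export
fit_knee <- function(support, psi0 = NULL, tol = 1e-6, max_iter = 50) {
  if (inherits(support, "penalty_path")) support <- path_support(support)
  beta <- support$beta; m <- support$m
  if (length(unique(beta)) < 4)
    stopf("need at least 4 distinct support points")
  psi <- psi0 %||% median(beta)
  lo <- min(beta); hi <- max(beta)
  converged <- FALSE
  it <- 0
  degenerate <- FALSE
  sse_at <- function(psi) {
    U <- pmax(beta - psi, 0)
    sum(stats::resid(lm(m ~ beta + U))^2)
  }
  sse_cur <- sse_at(psi)
  while (it < max_iter) {
    it <- it + 1
    U <- pmax(beta - psi, 0)
    V <- -as.numeric(beta > psi)
    fit <- lm(m ~ beta + U + V)
    cf <- coef(fit)
    if (anyNA(cf[c("beta", "U")])) { degenerate <- TRUE; break }
    b_hat <- cf[["U"]]
    if (abs(b_hat) < 1e-10) { degenerate <- TRUE; break }
    gamma <- if (is.na(cf[["V"]])) 0 else cf[["V"]]
    step <- gamma / b_hat
    # damped update: halve the step until the profile SSE does not worsen
    psi_new <- min(max(psi + step, lo), hi)
    sse_new <- sse_at(psi_new)
    halvings <- 0
    while (sse_new > sse_cur + 1e-12 && halvings < 20) {
      step <- step / 2
      psi_new <- min(max(psi + step, lo), hi)
      sse_new <- sse_at(psi_new)
      halvings <- halvings + 1
    }
    if (abs(psi_new - psi) < tol) {
      psi <- psi_new
      converged <- TRUE
      break
    }
    psi <- psi_new
    sse_cur <- sse_new
  }
  # final fit at the converged breakpoint, without the working indicator
  U <- pmax(beta - psi, 0)
  fit <- lm(m ~ beta + U)
  cf <- coef(fit)
  b_final <- if (is.na(cf[["U"]])) 0 else cf[["U"]]
  if (abs(b_final) < 1e-10) degenerate <- TRUE
  structure(list(a = cf[["beta"]], b = b_final, c = cf[["(Intercept)"]],
                 psi = psi, converged = converged && !degenerate,
                 degenerate = degenerate, iterations = it,
                 sse = sum(stats::residuals(fit)^2)),
            class = "knee_fit")
}

#' @export
print.knee_fit <- function(x, ...) {
  cat(sprintf("knee_fit: psi=%.4g (a=%.4g, b=%.4g, c=%.4g), %s after %d it.\n",
              x$psi, x$a, x$b, x$c,
              if (x$converged) "converged" else
                if (x$degenerate) "degenerate" else "not converged",
              x$iterations))
  invisible(x)
}

#' Choose the study-level penalty from per-trial knees
#'
#' The penalty applied to all trials of a dataset is the median of the
#' per-trial knee estimates, robust to occasional degenerate fits.
#'
#' @param knees numeric vector of converged knee values.
#' @return scalar penalty.
#' @export
choose_penalty <- function(knees) {
  knees <- knees[is.finite(knees)]
  if (length(knees) == 0) stopf("no converged knee values")
  median(knees)
}

#' Pool changepoints across channels
#'
#' Counts, for each frame, how many channels place a changepoint there.
#' Coherent behavioural events appear as coincident changepoints across the
#' speed-quantile channels, so pooled counts concentrate at event frames.
#'
#' @param per_channel list of `segmentation` objects (one per channel).
#' @param n_frames length of the count vector.
#' @return integer vector of length `n_frames` (class `pooled_changepoints`).
#' @export
pool_changepoints <- function(per_channel, n_frames) {
  counts <- integer(n_frames)
  for (seg in per_channel) {
    tau <- seg$changepoints
    if (length(tau) == 0) next
    if (any(tau < 0 | tau >= n_frames)) stopf("changepoint outside recording")
    counts[tau + 1L] <- counts[tau + 1L] + 1L
  }
  structure(counts, class = "pooled_changepoints")
}
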
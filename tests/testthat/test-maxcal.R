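test_that("the multiplier solve hits trivial and closed-form targets", {
  s <- c(rep(0, 60), rep(1, 60))
  # target at the unweighted mean gives zero tilt
  expect_equal(solve_delta_lambda(s, 0.5), 0)
  # two-point logistic closed form: w1/w0 = exp(-dl); target 1/(1+e) => dl = 1
  dl <- solve_delta_lambda(s, 1 / (1 + exp(1)))
  expect_equal(dl, 1, tolerance = 1e-8)
  expect_equal(reweighted_mean(s, dl), 1 / (1 + exp(1)), tolerance = 1e-10)
})

test_that("the solve agrees with an independent bisection oracle", {
  set.seed(7)
  for (rep in 1:5) {
    s <- runif(300)
    target <- runif(1, quantile(s, 0.1), quantile(s, 0.9))
    dl <- solve_delta_lambda(s, target)
    expect_equal(reweighted_mean(s, dl), target, tolerance = 1e-9)
    expect_equal(dl, bisect_delta_lambda(s, target), tolerance = 1e-6)
  }
})

test_that("unreachable and degenerate targets are rejected", {
  s <- c(0.1, 0.2, 0.3)
  expect_error(solve_delta_lambda(s, 0.3), "unreachable")
  expect_error(solve_delta_lambda(s, 0.05), "unreachable")
  expect_error(solve_delta_lambda(rep(0.2, 10), 0.2), "degenerate")
})

test_that("raising a rate target gives a negative multiplier shift", {
  set.seed(13)
  s <- rbinom(400, 100, 0.09) / 100
  expect_lt(solve_delta_lambda(s, mean(s) + 0.02), 0)
  expect_gt(solve_delta_lambda(s, mean(s) - 0.02), 0)
})

test_that("path weights are normalized, stable, and shift invariant", {
  expect_equal(path_weights(runif(10), 0), rep(0.1, 10))
  expect_equal(path_weights(c(0, 1), log(3)), c(0.75, 0.25))
  set.seed(5)
  s <- rnorm(50)
  dl <- 2
  expect_equal(path_weights(s, dl), path_weights(s + 7.3, dl))
  # log-space computation agrees with the naive formula in the safe regime
  naive <- exp(-dl * s) / sum(exp(-dl * s))
  expect_equal(path_weights(s, dl), naive, tolerance = 1e-12)
  # and survives exponents that overflow the naive formula
  expect_false(any(is.na(path_weights(s * 400, dl))))
  expect_equal(sum(path_weights(s * 400, dl)), 1)
})

test_that("tilted mean is non-increasing in the multiplier (variance identity)", {
  set.seed(17)
  for (rep in 1:100) {
    s <- rnorm(30, sd = runif(1, 0.1, 2))
    dls <- sort(runif(7, -3, 3))
    means <- vapply(dls, function(d) reweighted_mean(s, d), numeric(1))
    expect_true(all(diff(means) <= 1e-12))
  }
})

test_that("the coupled multi-constraint solve matches a brute-force oracle", {
  # joint two-constraint system over the four corners of {0,1}^2
  set.seed(23)
  s_mat <- cbind(rep(c(0, 1), each = 50), rep(c(0, 1), times = 50))
  expect_equal(solve_multi(s_mat, colMeans(s_mat)), c(0, 0), tolerance = 1e-6)
  targets <- c(0.4, 0.3)
  dl <- solve_multi(s_mat, targets)
  w <- path_weights(s_mat, dl)
  expect_equal(as.vector(crossprod(s_mat, w)), targets, tolerance = 1e-7)
  # exhaustive grid-search oracle over the two multipliers
  grid <- seq(-3, 3, by = 0.002)
  best <- c(NA, NA); best_err <- Inf
  for (d1 in grid) {
    wg <- path_weights(s_mat, c(d1, 0))
    # profile out the second multiplier with the 1-D solve on column 2
    d2 <- tryCatch(solve_delta_lambda_profiled(s_mat, d1, targets[2]),
                   error = function(e) NA)
    if (is.na(d2)) next
    wg <- path_weights(s_mat, c(d1, d2))
    err <- abs(sum(wg * s_mat[, 1]) - targets[1])
    if (err < best_err) { best_err <- err; best <- c(d1, d2) }
  }
  expect_equal(dl, best, tolerance = 5e-3)
  # perfectly correlated observables with inconsistent targets cannot converge
  s_corr <- cbind(s_mat[, 1], s_mat[, 1])
  expect_error(solve_multi(s_corr, c(0.3, 0.6)))
})

test_that("biased subsampling respects weights and reproducibility", {
  states <- matrix(sample(0:2, 40, replace = TRUE), nrow = 8)
  ens <- path_ensemble(states)
  # uniform weights, k = n: a permutation of the input
  all_s <- subsample_paths(ens, rep(1, 8), 8, seed = 2)
  expect_equal(sort(attr(all_s, "indices")), 1:8)
  # a single nonzero weight forces that path
  one <- subsample_paths(ens, c(0, 0, 1, 0, 0, 0, 0, 0), 1, seed = 3)
  expect_equal(attr(one, "indices"), 3L)
  expect_error(subsample_paths(ens, c(1, 1, rep(0, 6)), 3), "nonzero")
  w8 <- runif(8)
  expect_identical(subsample_paths(ens, w8, 4, seed = 9)$states,
                   subsample_paths(ens, w8, 4, seed = 9)$states)
})

test_that("selection frequencies match weights over repeated draws", {
  states <- matrix(0L, 5, 3); states[, 2] <- 1L
  ens <- path_ensemble(states)
  w <- c(0.4, 0.3, 0.15, 0.1, 0.05)
  n_rep <- 10000
  hits <- integer(5)
  for (r in seq_len(n_rep)) {
    i <- attr(subsample_paths(ens, w, 1, seed = r), "indices")
    hits[i] <- hits[i] + 1L
  }
  p_hat <- hits / n_rep
  se <- sqrt(w * (1 - w) / n_rep)
  expect_true(all(abs(p_hat - w) < 3.3 * se))
})

test_that("effective sample size diagnoses weight degeneracy", {
  expect_equal(effective_sample_size(rep(1 / 4, 4)), 4)
  expect_equal(effective_sample_size(c(1, 0, 0, 0)), 1)
  expect_lt(effective_sample_size(c(0.9, 0.05, 0.03, 0.02)), 1.3)
})
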
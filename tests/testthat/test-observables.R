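test_that("pair transition rate counts unordered pair events per step", {
  pairs <- rbind(c(0, 1), c(1, 2))
  # events at 0->1 and 1->2; the 2->0 step is not counted
  expect_equal(pair_transition_rate(discrete_trajectory(c(0, 1, 1, 2, 0)), pairs), 0.5)
  expect_equal(pair_transition_rate(discrete_trajectory(rep(3, 10)), pairs), 0)
  alt <- discrete_trajectory(rep(c(0, 1), 25))
  expect_equal(pair_transition_rate(alt, rbind(c(0, 1))), 1)
  expect_error(pair_transition_rate(alt, matrix(0, 0, 2)), "empty")
})

test_that("nearest-neighbour rate counts unit-label steps", {
  expect_equal(nn_transition_rate(discrete_trajectory(c(5, 6, 5, 7))), 2 / 3)
  expect_equal(nn_transition_rate(discrete_trajectory(rep(2, 8))), 0)
  expect_equal(nn_transition_rate(discrete_trajectory(0:9)), 1)
})

test_that("nn rate equals pair rate over all adjacent pairs, and rates lie in [0,1]", {
  set.seed(21)
  for (rep in 1:20) {
    tr <- discrete_trajectory(sample(0:7, 60, replace = TRUE))
    expect_equal(nn_transition_rate(tr), pair_transition_rate(tr, nn_pairs(8)))
    expect_gte(nn_transition_rate(tr), 0)
    expect_lte(nn_transition_rate(tr), 1)
  }
})

test_that("kappa is the lower/upper occupancy ratio with guarded denominator", {
  # uniform occupancy over all bins
  tr <- discrete_trajectory(rep(0:7, 10))
  expect_equal(symmetry_kappa(tr, 4), 1)
  # counts 3 vs 1 over a two-bin split
  expect_equal(symmetry_kappa(discrete_trajectory(c(0, 0, 0, 1)), 1), 3)
  expect_error(symmetry_kappa(discrete_trajectory(c(0, 0, 1), binning = binning_spec(4, 0, 4)), 2),
               "unoccupied")
  # pooled-ensemble kappa equals kappa of concatenated counts
  set.seed(3)
  states <- matrix(sample(0:7, 120, replace = TRUE), nrow = 4)
  ens <- path_ensemble(states)
  pooled <- symmetry_kappa(discrete_trajectory(as.vector(states)), 4, n_bins = 8)
  expect_equal(symmetry_kappa(ens, 4, n_bins = 8), pooled)
})

test_that("deviation from the decay theory curve is a windowed squared error", {
  bn <- binning_spec(20, 0, 7)
  mid <- bin_midpoints(bn)
  times <- seq(0, 10, by = 0.1)
  n0 <- 7; gamma <- 0.2
  theory <- n0 * exp(-gamma * times)
  # paths that sit exactly on the (binned) theory curve: deviation equals the
  # discretization residue only; build from midpoints so it is exactly zero
  lab <- pmin(pmax(findInterval(theory, bn$edges), 1), 20) - 1L
  ens <- path_ensemble(rbind(lab, lab), dt = 0.1, binning = bn)
  exact <- theory_deviation_dn(ens, n0, gamma, 5, 2)
  win <- which(times >= 5 & times <= 7)
  resid <- sum((mid[lab[win] + 1] - theory[win])^2) * 2 / 2
  expect_equal(as.numeric(exact), resid)
  # offset of two bins (clamped at the top, which lies outside the window)
  lab2 <- pmin(lab + 2L, 19L)
  ens_off <- path_ensemble(rbind(lab2, lab2), dt = 0.1, binning = bn)
  d_off <- theory_deviation_dn(ens_off, n0, gamma, 5, 2)
  per <- attr(d_off, "per_path")
  shift_expect <- sum((mid[lab2[win] + 1] - theory[win])^2) / 2
  expect_equal(per, rep(shift_expect, 2))
  expect_gte(as.numeric(d_off), 0)
  expect_error(theory_deviation_dn(ens, n0, gamma, 50, 2), "empty window")
  # unbinned integer records sitting exactly on a flat theory curve: zero
  flat <- path_ensemble(rbind(rep(5L, 30), rep(5L, 30)), dt = 0.1)
  expect_equal(as.numeric(theory_deviation_dn(flat, 5, 0, 1, 1)), 0)
})

test_that("evaluate_observable dispatches per kind and ignores weights", {
  states <- rbind(c(0, 1, 1, 2, 0), c(2, 2, 2, 2, 2), c(0, 1, 0, 1, 0))
  ens <- path_ensemble(states, weights = c(5, 1, 1))
  v <- evaluate_observable(nn_pair_obs(), ens)
  expect_equal(v, c(0.5, 0, 1))  # hand counts, weights ignored
  v_nn <- evaluate_observable(observable_spec("nn_transition_rate"), ens)
  expect_equal(v_nn, c(0.5, 0, 1))
  v_k <- evaluate_observable(observable_spec("symmetry_kappa", split = 1), ens)
  expect_equal(v_k, c(2 / 3, 0, 1.5))
  v_c <- evaluate_observable(observable_spec("custom", fn = function(t) max(t$states)), ens)
  expect_equal(v_c, c(2, 2, 1))
  expect_error(observable_spec("symmetry_kappa"), "split")
  expect_error(observable_spec("theory_deviation_dn"), "requires")
})
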
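test_that("kernel estimation by direct counting matches hand counts", {
  k <- estimate_kernel(discrete_trajectory(c(0, 1, 0, 1, 0)))
  expect_equal(unname(k$matrix), rbind(c(0, 1), c(1, 0)))
  # [0,0,0,1]: state 1 is never a source -> error, or uniform fill on request
  expect_error(estimate_kernel(discrete_trajectory(c(0, 0, 0, 1))), "never visited")
  k2 <- estimate_kernel(discrete_trajectory(c(0, 0, 0, 1)), unvisited = "uniform")
  expect_equal(unname(k2$matrix[1, ]), c(2 / 3, 1 / 3))
  expect_equal(attr(k2, "unvisited"), 1L)
})

test_that("kernel estimation is consistent on long samples", {
  k <- three_state_kernel()
  tr <- simulate_markov(k, 3e5, seed = 31)
  est <- estimate_kernel(tr, 3)
  cnt <- attr(est, "counts")
  se <- sqrt(k$matrix * (1 - k$matrix) / rowSums(cnt))
  expect_true(all(abs(est$matrix - k$matrix) <= 3.5 * se))
})

test_that("kernel reweighting renormalizes counted entries", {
  k <- transition_kernel(rbind(c(0.9, 0.1), c(0.2, 0.8)))
  expect_equal(reweight_kernel(k, 0, rbind(c(0, 1)))$matrix, k$matrix)
  # e^{-dl} = 2 on the (0,1) entry: row 0 becomes (0.9, 0.2)/1.1
  kr <- reweight_kernel(k, -log(2), rbind(c(0, 1)))
  expect_equal(unname(kr$matrix[1, ]), c(0.9, 0.2) / 1.1)
  expect_equal(unname(kr$matrix[2, ]), c(0.2, 0.8))  # uncounted row untouched
  # per-step rate convention divides the exponent by the trajectory length
  kr2 <- reweight_kernel(k, -log(2) * 50, rbind(c(0, 1)),
                         exponent = "per_step", l_traj = 50)
  expect_equal(kr2$matrix, kr$matrix)
})

test_that("reweighting composes additively in the multiplier", {
  set.seed(41)
  pairs <- symmetric_pairs(rbind(c(0, 1), c(1, 2)))
  for (rep in 1:5) {
    k <- rand_kernel(4, seed = 100 + rep)
    d1 <- runif(1, -2, 2); d2 <- runif(1, -2, 2)
    twice <- reweight_kernel(reweight_kernel(k, d1, pairs), d2, pairs)
    once <- reweight_kernel(k, d1 + d2, pairs)
    expect_equal(twice$matrix, once$matrix, tolerance = 1e-12)
  }
})

test_that("stationary distribution solves pi P = pi", {
  expect_equal(stationary_distribution(transition_kernel(rbind(c(0.7, 0.3), c(0.3, 0.7)))),
               c(0.5, 0.5))
  expect_equal(stationary_distribution(transition_kernel(rbind(c(0.9, 0.1), c(0.2, 0.8)))),
               c(2 / 3, 1 / 3))
  red <- transition_kernel(rbind(c(1, 0), c(0, 1)))
  expect_error(stationary_distribution(red), "reducible")
  for (rep in 1:5) {
    k <- rand_kernel(5, seed = rep)
    p <- stationary_distribution(k)
    expect_equal(as.vector(p %*% k$matrix), p, tolerance = 1e-10)
  }
})

test_that("expected pair rate matches the stationary closed form", {
  un <- transition_kernel(matrix(1 / 3, 3, 3))
  expect_equal(expected_pair_rate(un, nn_pairs(3)), 4 / 9)
  expect_equal(expected_pair_rate(three_state_kernel(), rbind(c(0, 1), c(1, 2))),
               0.0890, tolerance = 2e-3)
})

test_that("eigenspectrum is sorted with leading eigenvalue 1", {
  idk <- transition_kernel(diag(3))
  expect_equal(Mod(eigenspectrum(idk)$eigenvalue), rep(1, 3))
  a <- 0.3; b <- 0.15
  k2 <- transition_kernel(rbind(c(1 - a, a), c(b, 1 - b)))
  es <- eigenspectrum(k2, dt = 2)
  expect_equal(sort(Re(es$eigenvalue)), sort(c(1, 1 - a - b)))
  expect_equal(es$timescale[2], -2 / log(1 - a - b))
  for (rep in 1:5) {
    es <- eigenspectrum(rand_kernel(6, seed = 50 + rep))
    expect_equal(es$modulus[1], 1, tolerance = 1e-10)
    expect_true(all(diff(es$modulus) <= 1e-12))
  }
})

test_that("free energies are relative -kT log occupancies", {
  expect_equal(free_energy_profile(discrete_trajectory(rep(0:3, 5))), rep(0, 4))
  tr <- discrete_trajectory(c(rep(0, 8), rep(1, 2)))
  expect_equal(free_energy_profile(tr), c(0, log(4)))
  expect_equal(free_energy_profile(tr, kT = 2.5), c(0, 2.5 * log(4)))
  # doubling all counts leaves the profile unchanged
  tr2 <- discrete_trajectory(rep(c(rep(0, 8), rep(1, 2)), 2))
  expect_equal(free_energy_profile(tr2), free_energy_profile(tr))
  # unoccupied bins are +Inf
  f <- free_energy_profile(discrete_trajectory(c(0, 0, 2, 2), binning = binning_spec(3, 0, 3)))
  expect_true(is.infinite(f[2]))
})

test_that("exhaustive enumeration yields exact normalized path probabilities", {
  k <- three_state_kernel()
  for (Tlen in c(2, 4, 6)) {
    en <- enumerate_paths(k, Tlen)
    expect_equal(nrow(en$paths), 3^Tlen)
    expect_equal(sum(en$prob), 1, tolerance = 1e-10)
  }
  # length 2 with stationary init: probabilities are pi_m p_mn
  en2 <- enumerate_paths(k, 2)
  pi_hat <- stationary_distribution(k)
  expect_equal(en2$prob, as.vector(t(pi_hat * k$matrix)), tolerance = 1e-12)
  # enumeration average of the pair rate equals the stationary closed form
  pairs <- rbind(c(0, 1), c(1, 2))
  en6 <- enumerate_paths(k, 6)
  s <- apply(en6$paths, 1, function(p)
    pair_transition_rate(discrete_trajectory(p), pairs))
  expect_equal(sum(s * en6$prob), expected_pair_rate(k, pairs), tolerance = 1e-12)
  expect_error(enumerate_paths(rand_kernel(10, 1), 8), "too large")
})
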
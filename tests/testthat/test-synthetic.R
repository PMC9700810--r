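test_that("Markov sampling follows the kernel exactly in degenerate cases", {
  idk <- transition_kernel(diag(3))
  tr <- simulate_markov(idk, 50, init = 1L, seed = 2)
  expect_equal(tr$states, rep(1L, 50))
  alt <- transition_kernel(rbind(c(0, 1), c(1, 0)))
  tr2 <- simulate_markov(alt, 40, init = 0L, seed = 2)
  expect_equal(tr2$states, rep(c(0L, 1L), 20))
  expect_identical(simulate_markov(three_state_kernel(), 100, seed = 5)$states,
                   simulate_markov(three_state_kernel(), 100, seed = 5)$states)
})

test_that("double-well occupancies follow the Boltzmann weights of the profile", {
  for (asym in c(0, log(2))) {
    sp <- double_well_spec(asymmetry = asym, length = 3e5, seed = 71)
    x <- simulate_double_well(sp)
    tr <- discretize(x, binning_spec(32, -1, 1))
    FF <- double_well_potential(sp)
    p_th <- exp(-FF) / sum(exp(-FF))
    occ <- tabulate(tr$states + 1L, 32) / length(tr$states)
    # slow mixing: compare aggregated halves rather than per-bin counts
    kap_th <- sum(p_th[1:16]) / sum(p_th[17:32])
    expect_equal(symmetry_kappa(tr, 16), kap_th, tolerance = 0.35)
    expect_lt(max(abs(occ - p_th)), 0.05)
  }
})

test_that("double-well dynamics satisfy detailed balance in its fluxes", {
  sp <- double_well_spec(length = 2e5, seed = 13)
  tr <- discretize(simulate_double_well(sp), binning_spec(32, -1, 1))
  cnt <- attr(estimate_kernel(tr, 32, unvisited = "uniform"), "counts")
  for (i in 1:31) {
    up <- cnt[i, i + 1]; down <- cnt[i + 1, i]
    if (up + down > 20) {
      z <- abs(up - down) / sqrt(up + down)
      expect_lt(z, 4)
    }
  }
})

test_that("lower diffusion lowers the nearest-neighbour transition rate", {
  rates <- vapply(c(0.2, 0.45), function(d) {
    sp <- double_well_spec(diffusion = d, length = 4e4, seed = 99)
    nn_transition_rate(discretize(simulate_double_well(sp), binning_spec(32, -1, 1)))
  }, numeric(1))
  expect_lt(rates[1], rates[2])
})

test_that("closed-system quantum dynamics match the Lindblad integrator exactly", {
  # gamma = 0: no jumps, the unravelling is deterministic unitary evolution
  sp <- quantum_jump_spec(gamma = 0, t_max = 5)
  rec <- simulate_quantum_jump(sp, 2, discretize = FALSE)
  expect_equal(rec[1, ], rec[2, ])  # no stochasticity without dissipation
  ref <- lindblad_mean(sp)
  expect_lt(max(abs(rec[1, ] - ref)), 1e-5)
  # Rabi exchange moves photons coherently when the initial Fock level sits
  # below the truncation (at the top level the raising term is cut off)
  sp5 <- quantum_jump_spec(n_photons_init = 5, gamma = 0, t_max = 5)
  rec5 <- simulate_quantum_jump(sp5, 1, discretize = FALSE)
  expect_gt(max(rec5[1, ]) - min(rec5[1, ]), 0.1)
  expect_lt(max(abs(rec5[1, ] - lindblad_mean(sp5))), 1e-5)
})

test_that("pure cavity decay reproduces the exponential law", {
  # g = 0 decouples the atom: <n_t> = n0 exp(-gamma t)
  sp <- quantum_jump_spec(g = 0, gamma = 0.1, t_max = 8, seed = 23)
  ref <- lindblad_mean(sp)
  times <- attr(ref, "times")
  expect_equal(as.numeric(ref), 7 * exp(-0.1 * times), tolerance = 1e-6)
  rec <- simulate_quantum_jump(sp, 400, discretize = FALSE)
  mu <- colMeans(rec); se <- apply(rec, 2, sd) / sqrt(nrow(rec))
  th <- 7 * exp(-0.1 * attr(rec, "times"))
  expect_true(all(abs(mu - th) <= 3 * pmax(se, 1e-3)))
})

test_that("the Lindblad integrator preserves trace and positivity", {
  sp <- quantum_jump_spec(gamma = 0.1, t_max = 6)
  ref <- lindblad_mean(sp)
  expect_lt(attr(ref, "trace_error"), 1e-7)
  expect_true(all(ref >= 0))
  expect_error(quantum_jump_spec(gamma = -1), "gamma")
  expect_error(quantum_jump_spec(n_photons_init = 8, hilbert_cutoff = 8), "cutoff")
})

test_that("quantum-jump records discretize onto the photon-number binning", {
  sp <- quantum_jump_spec(gamma = 0.1, t_max = 4, seed = 5)
  ens <- simulate_quantum_jump(sp, 8)
  expect_s3_class(ens, "path_ensemble")
  expect_equal(ens$binning$n_bins, 20L)
  expect_equal(ens$dt, 0.1)
  raw <- attr(ens, "n_expect")
  mid <- bin_midpoints(ens$binning)
  expect_lt(max(abs(mid[ens$states + 1L] - raw)), (7 / 20) / 2 + 1e-9)
  expect_identical(simulate_quantum_jump(sp, 3)$states,
                   simulate_quantum_jump(sp, 3)$states)
})
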
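# Trained-model fixtures shared across the blocks below (built once).
cycle_model <- local({
  tr <- discrete_trajectory(rep(c(0L, 1L), 250))
  cfg <- model_config(2, embed_dim = 4, hidden_dim = 16, batch_len = 20,
                      batch_size = 8, epochs = 60, seed = 2)
  train_lstm(tr, cfg)
})

markov_fit <- local({
  kernel <- three_state_kernel()
  tr <- simulate_markov(kernel, 1e5, seed = 19)
  cfg <- model_config(3, hidden_dim = 32, batch_len = 20, epochs = 15,
                      lr_schedule = "step", swa = TRUE, seed = 5)
  list(kernel = kernel, traj = tr, model = train_lstm(tr, cfg),
       counted = estimate_kernel(tr, 3))
})

test_that("training reduces the cross-entropy loss in trend", {
  h <- markov_fit$model$loss_history
  expect_true(all(is.finite(h)))
  expect_lt(mean(tail(h, 3)), h[1])
  expect_error(train_lstm(discrete_trajectory(c(0, 1, 2, 3)),
                          model_config(3, epochs = 1)), "n_states")
})

test_that("a deterministic 2-cycle is learned to near-certainty", {
  expect_gt(next_state_probs(cycle_model, 0L)[2], 0.99)
  expect_gt(next_state_probs(cycle_model, c(0L, 1L))[1], 0.99)
  # the model assigns probability > 0.95 to the length-6 alternating path
  lp6 <- path_log_probability(cycle_model, discrete_trajectory(c(0L, 1L, 0L, 1L, 0L, 1L)))
  expect_gt(exp(lp6), 0.95)
  # sampled paths alternate at almost every step
  ens <- generate_paths(cycle_model, 20, 50, init = 0L, seed = 4)
  flips <- mean(abs(t(apply(ens$states, 1, diff))) == 1)
  expect_gt(flips, 0.95)
})

test_that("an i.i.d. uniform series yields near-uniform predictions", {
  set.seed(8)
  tr <- discrete_trajectory(sample(0:2, 1e4, replace = TRUE))
  cfg <- model_config(3, hidden_dim = 16, batch_len = 20, epochs = 8, seed = 3)
  m <- train_lstm(tr, cfg)
  for (ctx in 0:2) {
    p <- next_state_probs(m, ctx)
    expect_equal(sum(p), 1, tolerance = 1e-6)
    expect_true(all(abs(p - 1 / 3) < 0.05))
  }
})

test_that("a Markov chain's conditional distributions are recovered", {
  counted <- markov_fit$counted$matrix
  for (ctx in 0:2) {
    p <- next_state_probs(markov_fit$model, ctx)
    expect_equal(sum(p), 1, tolerance = 1e-6)
    expect_true(all(abs(p - counted[ctx + 1, ]) < 0.02))
  }
})

test_that("generated ensembles reproduce the training kernel and stationary law", {
  ens <- generate_paths(markov_fit$model, 100, 2000, init = 0L, seed = 7)
  gk <- estimate_kernel(ens, 3)
  expect_lt(max(abs(gk$matrix - markov_fit$counted$matrix)), 0.03)
  # occupancies against the analytic stationary distribution; the deviation
  # combines generation noise and the model bias inherited from the finite
  # training sample, so both enter the standard error (each with the
  # chain's integrated autocorrelation via eigenvalue 2)
  pi_hat <- stationary_distribution(markov_fit$kernel)
  occ <- tabulate(as.vector(ens$states) + 1L, 3) / length(ens$states)
  lam2 <- eigenspectrum(markov_fit$kernel)$modulus[2]
  iact <- (1 - lam2) / (1 + lam2)
  n_gen <- length(ens$states) * iact
  n_train <- length(markov_fit$traj$states) * iact
  se <- sqrt(pi_hat * (1 - pi_hat) * (1 / n_gen + 1 / n_train))
  expect_true(all(abs(occ - pi_hat) < 3 * se))
})

test_that("generation is seed deterministic and multinomial", {
  a <- generate_paths(markov_fit$model, 6, 50, init = 1L, seed = 12)
  b <- generate_paths(markov_fit$model, 6, 50, init = 1L, seed = 12)
  expect_identical(a$states, b$states)
  c2 <- generate_paths(markov_fit$model, 6, 50, init = 1L, seed = 13)
  expect_false(identical(a$states, c2$states))
  # multinomial sampling, not argmax: state 1 must appear in long output
  long <- generate_paths(markov_fit$model, 2, 2000, init = 0L, seed = 14)
  expect_true(all(0:2 %in% long$states))
  expect_error(generate_paths(markov_fit$model, 0, 10, 0), "n_paths")
})

test_that("path log probability equals a step-by-step scoring oracle", {
  tr <- discrete_trajectory(c(0L, 2L, 2L, 1L, 0L, 0L))
  lp <- path_log_probability(markov_fit$model, tr)
  manual <- 0
  for (t in 1:5) {
    p <- next_state_probs(markov_fit$model, tr$states[1:t])
    manual <- manual + log(p[tr$states[t + 1] + 1])
  }
  expect_equal(lp, manual, tolerance = 1e-10)
  expect_lte(lp, 0)
  # a uniform-prediction model scores -T log N for any trajectory
  um <- uniform_model(4)
  tru <- discrete_trajectory(c(0L, 3L, 1L, 1L, 2L))
  expect_equal(path_log_probability(um, tru), -4 * log(4), tolerance = 1e-12)
})

test_that("models survive an archive round-trip", {
  tmp <- withr::local_tempfile(fileext = ".rds")
  save_sequence_model(cycle_model, tmp)
  back <- load_sequence_model(tmp)
  a <- generate_paths(cycle_model, 3, 10, 0L, seed = 6)
  b <- generate_paths(back, 3, 10, 0L, seed = 6)
  expect_identical(a$states, b$states)
})
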
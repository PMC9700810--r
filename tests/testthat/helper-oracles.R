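# Shared helpers for the test suite: small independent oracles and fixtures.

# Random row-stochastic matrix (Dirichlet rows via normalized gammas).
rand_kernel <- function(n, seed) {
  set.seed(seed)
  m <- matrix(stats::rgamma(n * n, shape = 1) + 1e-3, n, n)
  transition_kernel(m / rowSums(m))
}

# Brute-force bin counting oracle (independent of findInterval).
brute_bin <- function(x, edges) {
  n_bins <- length(edges) - 1L
  vapply(x, function(v) {
    if (v < edges[1]) return(0L)
    if (v >= edges[n_bins + 1L]) return(n_bins - 1L)
    for (i in seq_len(n_bins)) {
      if (v >= edges[i] && v < edges[i + 1L]) return(i - 1L)
    }
    n_bins - 1L
  }, integer(1))
}

# Bisection oracle for the tilted-mean equation (independent of the
# package's bracketing + Newton implementation).
bisect_delta_lambda <- function(s, target, lo = -1e4, hi = 1e4, iter = 200) {
  f <- function(dl) {
    w <- exp(-dl * s - max(-dl * s))
    sum(w * s) / sum(w) - target
  }
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# A model whose predictions are uniform over states, built directly from a
# zeroed output head (the softmax of a constant is uniform).
uniform_model <- function(n_states) {
  cfg <- model_config(n_states, embed_dim = 2L, hidden_dim = 4L,
                      epochs = 1L, seed = 1L)
  par <- maxcaliber:::.lstm_init(cfg)
  par$V[] <- 0
  par$c_out[] <- 0
  structure(list(config = cfg, parameters = par, loss_history = numeric(0),
                 dt = 1, binning = NULL), class = "sequence_model")
}

# Profiled 1-D bisection for the second multiplier of a two-constraint
# system, holding the first multiplier fixed (oracle building block).
solve_delta_lambda_profiled <- function(s_mat, d1, target2,
                                        lo = -50, hi = 50, iter = 200) {
  f <- function(d2) {
    a <- -d1 * s_mat[, 1] - d2 * s_mat[, 2]
    w <- exp(a - max(a))
    sum(w * s_mat[, 2]) / sum(w) - target2
  }
  if (f(lo) < 0 || f(hi) > 0) stop("profiled target unreachable")
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

nn_pair_obs <- function() {
  observable_spec("pair_transition_rate", pairs = rbind(c(0, 1), c(1, 2)))
}
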
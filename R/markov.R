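#' Row-stochastic transition kernel
#'
#' @param matrix square matrix of nonnegative transition probabilities; each
#'   row must sum to 1 within 1e-10.
#' @param labels optional state labels (defaults to 0-based integers).
#' @return An object of class `transition_kernel`.
#' @export
transition_kernel <- function(matrix, labels = NULL) {
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m)) stop("kernel must be square")
  if (any(!is.finite(m)) || any(m < 0)) stop("kernel entries must be finite and >= 0")
  if (any(abs(rowSums(m) - 1) > 1e-10)) stop("kernel rows must sum to 1 (within 1e-10)")
  if (is.null(labels)) labels <- 0:(nrow(m) - 1L)
  dimnames(m) <- list(labels, labels)
  structure(list(matrix = m, n_states = nrow(m)), class = "transition_kernel")
}

#' @export
print.transition_kernel <- function(x, ...) {
  cat(sprintf("<transition_kernel> %d states\n", x$n_states))
  print(round(x$matrix, 4))
  invisible(x)
}

#' Reference 3-state kernel with two metastable end states
#'
#' A documented three-state kernel whose stationary nearest-neighbour
#' transition rate over the pairs \{0,1\} and \{1,2\} is about 0.089
#' transitions per step: states 0 and 2 are long-lived, state 1 is a
#' short-lived intermediate. Used throughout the examples and as the default
#' input of the three-state constraint experiment.
#'
#' @return A [transition_kernel()].
#' @examples
#' k <- three_state_kernel()
#' expected_pair_rate(k, rbind(c(0, 1), c(1, 2)))
#' @export
three_state_kernel <- function() {
  transition_kernel(rbind(c(0.9425, 0.0475, 0.0100),
                          c(0.3500, 0.3000, 0.3500),
                          c(0.0100, 0.0475, 0.9425)))
}

#' Estimate a transition kernel by direct counting
#'
#' `p_mn = count(m -> n) / count(m -> .)`; every state must occur at least
#' once as a transition source. Ensemble counts are pooled over paths; with
#' `weights`, each path's transition counts are multiplied by its weight
#' (useful for counting over a reweighted ensemble).
#'
#' @param x a [discrete_trajectory()] or [path_ensemble()].
#' @param n_states number of states (defaults to binning metadata or the
#'   largest observed label + 1).
#' @param weights optional per-path weights (ensembles only).
#' @param unvisited `"error"` (default) rejects states with no outgoing
#'   transitions; `"uniform"` fills those rows with `1/n` instead (their
#'   0-based labels are then listed in attribute `unvisited`).
#' @return A [transition_kernel()]; raw counts in attribute `counts`.
#' @export
estimate_kernel <- function(x, n_states = NULL, weights = NULL,
                            unvisited = c("error", "uniform")) {
  unvisited <- match.arg(unvisited)
  if (inherits(x, "discrete_trajectory")) {
    rows <- matrix(x$states, nrow = 1L)
  } else if (inherits(x, "path_ensemble")) {
    rows <- x$states
  } else stop("x must be a discrete_trajectory or path_ensemble")
  if (is.null(n_states))
    n_states <- if (!is.null(x$binning)) x$binning$n_bins else max(rows) + 1L
  if (is.null(weights)) weights <- rep(1, nrow(rows))
  counts <- matrix(0, n_states, n_states)
  for (i in seq_len(nrow(rows))) {
    a <- rows[i, -ncol(rows)] + 1L
    b <- rows[i, -1L] + 1L
    tab <- table(factor(a, levels = 1:n_states), factor(b, levels = 1:n_states))
    counts <- counts + weights[i] * unclass(tab)
  }
  out <- rowSums(counts)
  zero_rows <- which(out == 0)
  if (length(zero_rows)) {
    if (unvisited == "error")
      stop("states never visited as a transition source: ",
           paste(zero_rows - 1L, collapse = ", "))
    counts[zero_rows, ] <- 1 / n_states
    out <- rowSums(counts)
  }
  k <- transition_kernel(counts / out)
  attr(k, "counts") <- counts
  if (length(zero_rows)) attr(k, "unvisited") <- unname(zero_rows) - 1L
  k
}

#' Closed-form Maximum Caliber reweighting of a Markov kernel
#'
#' Multiplies each counted transition entry by `exp(-dl_eff)` and
#' renormalizes every row, where `dl_eff` is `delta_lambda` for a per-event
#' constraint (`exponent = "per_event"`) or `delta_lambda / l_traj` when the
#' constrained observable is a per-step rate (`exponent = "per_step"`), since
#' a rate constraint tilts each counted event by the multiplier divided by
#' the trajectory length.
#'
#' @param kernel a [transition_kernel()].
#' @param delta_lambda the multiplier shift.
#' @param counted ordered transition pairs, a 2-column matrix of 0-based
#'   labels. Use [symmetric_pairs()] to expand unordered pairs.
#' @param exponent exponent convention (see above).
#' @param l_traj trajectory length in steps; required for `"per_step"`.
#' @return the reweighted [transition_kernel()].
#' @examples
#' k <- transition_kernel(rbind(c(0.9, 0.1), c(0.2, 0.8)))
#' reweight_kernel(k, -log(2), rbind(c(0, 1)))  # doubles p01, renormalizes
#' @export
reweight_kernel <- function(kernel, delta_lambda, counted,
                            exponent = c("per_event", "per_step"),
                            l_traj = NULL) {
  stopifnot(inherits(kernel, "transition_kernel"))
  exponent <- match.arg(exponent)
  counted <- .pairs_matrix(counted)
  if (any(counted < 0 | counted >= kernel$n_states)) stop("invalid pair labels")
  dl_eff <- if (exponent == "per_step") {
    if (is.null(l_traj)) stop("l_traj required for the per-step rate convention")
    delta_lambda / l_traj
  } else delta_lambda
  m <- kernel$matrix
  m[counted + 1L] <- m[counted + 1L] * exp(-dl_eff)
  transition_kernel(m / rowSums(m))
}

#' Expand unordered state pairs into both ordered directions
#' @param pairs 2-column matrix (or list) of unordered pairs.
#' @return 2-column matrix of ordered pairs (both directions, deduplicated).
#' @export
symmetric_pairs <- function(pairs) {
  p <- .pairs_matrix(pairs)
  unique(rbind(p, p[, 2:1, drop = FALSE]))
}

#' All nearest-neighbour unordered pairs for `n` states
#' @param n_states number of states.
#' @export
nn_pairs <- function(n_states) {
  cbind(0:(n_states - 2L), 1:(n_states - 1L))
}

.strongly_connected <- function(P) {
  R <- (P > 0) | diag(nrow(P)) > 0
  for (i in seq_len(ceiling(log2(nrow(P))) + 1L)) R <- (R %*% R) > 0
  all(R & t(R))
}

#' Stationary distribution of an irreducible kernel
#'
#' Solves `pi P = pi`, `sum(pi) = 1` by a dense linear solve.
#'
#' @param kernel a [transition_kernel()] (must be irreducible).
#' @return probability vector over states.
#' @export
stationary_distribution <- function(kernel) {
  stopifnot(inherits(kernel, "transition_kernel"))
  P <- kernel$matrix
  if (!.strongly_connected(P)) stop("reducible kernel: no unique stationary distribution")
  n <- nrow(P)
  A <- rbind(t(P) - diag(n), rep(1, n))
  pi_hat <- qr.solve(A, c(rep(0, n), 1))
  pi_hat <- pmax(unname(pi_hat), 0)
  pi_hat / sum(pi_hat)
}

#' Stationary transitions per step over listed pairs
#'
#' Closed form for the ensemble-averaged pair transition rate of a Markov
#' chain: `<N> = sum over ordered (m, n) in pairs of pi_m p_mn`.
#'
#' @param kernel a [transition_kernel()].
#' @param pairs unordered pairs (expanded to both directions).
#' @return expected transitions per step.
#' @export
expected_pair_rate <- function(kernel, pairs) {
  stopifnot(inherits(kernel, "transition_kernel"))
  p <- symmetric_pairs(pairs)
  pi_hat <- stationary_distribution(kernel)
  sum(pi_hat[p[, 1] + 1L] * kernel$matrix[p + 1L])
}

#' Eigenspectrum and implied timescales of a kernel
#'
#' Eigenvalues sorted by modulus (leading eigenvalue is 1 for any
#' row-stochastic matrix); implied relaxation timescales
#' `t_i = -dt / ln|lambda_i|` for `|lambda_i| < 1`.
#'
#' @param kernel a [transition_kernel()].
#' @param dt time step per transition.
#' @return data.frame with columns `eigenvalue` (complex), `modulus`,
#'   `timescale` (NA for the stationary eigenvalue).
#' @export
eigenspectrum <- function(kernel, dt = 1) {
  stopifnot(inherits(kernel, "transition_kernel"))
  ev <- eigen(kernel$matrix, only.values = TRUE)$values
  ev <- ev[order(-Mod(ev))]
  mod <- Mod(ev)
  ts <- ifelse(mod < 1 - 1e-12 & mod > 0, -dt / log(mod), NA_real_)
  data.frame(eigenvalue = ev, modulus = mod, timescale = ts)
}

#' Free-energy profile over bins from direct counting
#'
#' `F_i = -kT ln P_i`, shifted so the minimum is 0; unoccupied bins are
#' `+Inf`. Doubling all counts leaves the profile unchanged.
#'
#' @param x a [discrete_trajectory()] or [path_ensemble()].
#' @param n_bins bin count when no binning metadata is present.
#' @param kT thermal energy setting the scale (default 1).
#' @return numeric vector of free energies per bin.
#' @export
free_energy_profile <- function(x, n_bins = NULL, kT = 1) {
  counts <- .occupancy_counts(x, n_bins)
  if (sum(counts) == 0) stop("empty input: no occupied bins")
  p <- counts / sum(counts)
  f <- ifelse(p > 0, -kT * log(p), Inf)
  f - min(f)
}

#' Exhaustively enumerate all paths of a Markov chain
#'
#' Returns every path of `length` samples together with its exact
#' probability `P = p_init(i0) * prod_k p_{i_k, i_{k+1}}`; probabilities sum
#' to 1. Intended as a small-system oracle (`n_states^length <= 1e6`).
#'
#' @param kernel a [transition_kernel()].
#' @param length samples per path (`>= 2`; `length - 1` transitions).
#' @param init initial state label or probability distribution; default is
#'   the stationary distribution.
#' @return list with `paths` (matrix, one row per path, 0-based labels) and
#'   `prob` (exact path probabilities).
#' @export
enumerate_paths <- function(kernel, length, init = NULL) {
  stopifnot(inherits(kernel, "transition_kernel"))
  n <- kernel$n_states
  length <- as.integer(length)
  if (length < 2L) stop("length must be >= 2")
  if (n^length > 1e6) stop("state space too large to enumerate; sample instead")
  p0 <- if (is.null(init)) stationary_distribution(kernel)
        else if (base::length(init) == 1L) {
          v <- numeric(n); v[as.integer(init) + 1L] <- 1; v
        } else {
          stopifnot(base::length(init) == n, all(init >= 0), abs(sum(init) - 1) < 1e-8)
          as.numeric(init)
        }
  paths <- matrix(0:(n - 1L), ncol = 1L)
  prob <- p0
  for (t in 2:length) {
    k <- nrow(paths)
    paths <- paths[rep(seq_len(k), each = n), , drop = FALSE]
    nxt <- rep(0:(n - 1L), times = k)
    prob <- rep(prob, each = n) * kernel$matrix[cbind(paths[, t - 1L] + 1L, nxt + 1L)]
    paths <- cbind(paths, nxt)
  }
  dimnames(paths) <- NULL
  list(paths = paths, prob = unname(prob))
}
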
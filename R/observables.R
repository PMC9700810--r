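#' Specification of a path-dependent observable s(Gamma)
#'
#' Declares one of the built-in path functionals, or a custom one, together
#' with its parameters. The built-in kinds are:
#' \describe{
#'   \item{`nn_transition_rate`}{number of nearest-neighbour bin transitions
#'     per step (a diffusivity-like kinetic observable).}
#'   \item{`pair_transition_rate`}{transitions per step between user-listed
#'     unordered state pairs (`pairs`: 2-column matrix of labels).}
#'   \item{`symmetry_kappa`}{ratio of lower-half to upper-half bin occupancy
#'     (`split`: first bin of the upper half).}
#'   \item{`theory_deviation_dn`}{windowed squared deviation of photon-number
#'     paths from the exponential-decay curve `n0 * exp(-gamma * t)`
#'     (params `n0`, `gamma`, `t_start`, `dt_window`, `time_step`).}
#'   \item{`custom`}{a user-supplied function `discrete_trajectory -> real`
#'     passed as param `fn`.}
#' }
#'
#' @param kind observable kind (see above).
#' @param ... kind-specific parameters.
#' @return An object of class `observable_spec`.
#' @export
observable_spec <- function(kind = c("nn_transition_rate", "pair_transition_rate",
                                     "symmetry_kappa", "theory_deviation_dn",
                                     "custom"), ...) {
  kind <- match.arg(kind)
  params <- list(...)
  need <- function(nm) {
    miss <- setdiff(nm, names(params))
    if (length(miss)) stop(sprintf("observable '%s' requires params: %s",
                                   kind, paste(miss, collapse = ", ")))
  }
  switch(kind,
         pair_transition_rate = need("pairs"),
         symmetry_kappa = need("split"),
         theory_deviation_dn = need(c("n0", "gamma", "t_start", "dt_window")),
         custom = {
           need("fn")
           if (!is.function(params$fn)) stop("custom observable param 'fn' must be a function")
         },
         NULL)
  structure(list(name = if (!is.null(params$name)) params$name else kind,
                 kind = kind, params = params), class = "observable_spec")
}

.pairs_matrix <- function(pairs) {
  if (is.list(pairs)) pairs <- do.call(rbind, lapply(pairs, as.integer))
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (nrow(pairs) == 0L) stop("empty pair set")
  pairs
}

#' Transitions per step between listed state pairs
#'
#' Counts steps `t` where the unordered pair `{state_t, state_{t+1}}` is in
#' the supplied set, divided by the number of steps `T - 1` (so a path that
#' makes a counted transition at every step scores exactly 1).
#'
#' @param traj a [discrete_trajectory()].
#' @param pairs 2-column matrix (or list of length-2 vectors) of unordered
#'   state-label pairs.
#' @return transitions per step, in `[0, 1]`.
#' @examples
#' tr <- discrete_trajectory(c(0, 1, 1, 2, 0))
#' pair_transition_rate(tr, rbind(c(0, 1), c(1, 2)))  # 0.5
#' @export
pair_transition_rate <- function(traj, pairs) {
  stopifnot(inherits(traj, "discrete_trajectory"))
  pairs <- .pairs_matrix(pairs)
  s <- traj$states
  a <- s[-length(s)]; b <- s[-1]
  key <- paste(pmin(a, b), pmax(a, b))
  pk <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  sum(key %in% pk) / (length(s) - 1L)
}

#' Nearest-neighbour transitions per step
#'
#' Fraction of steps whose state labels differ by exactly one bin; equal to
#' [pair_transition_rate()] with all adjacent-label pairs.
#'
#' @param traj a [discrete_trajectory()].
#' @return transitions per step, in `[0, 1]`.
#' @export
nn_transition_rate <- function(traj) {
  stopifnot(inherits(traj, "discrete_trajectory"))
  s <- traj$states
  sum(abs(diff(s)) == 1L) / (length(s) - 1L)
}

.occupancy_counts <- function(x, n_bins = NULL) {
  s <- if (inherits(x, "discrete_trajectory")) x$states else as.vector(x$states)
  bn <- x$binning
  if (is.null(n_bins)) n_bins <- if (!is.null(bn)) bn$n_bins else max(s) + 1L
  tabulate(s + 1L, nbins = n_bins)
}

#' Population symmetry ratio kappa
#'
#' `kappa = sum_{i < split} P_i / sum_{i >= split} P_i` with `P_i` the
#' empirical occupancy of bin `i` by direct counting; equals 1 for a profile
#' with symmetric lower/upper populations. For an ensemble the counts are
#' pooled over all member paths.
#'
#' @param x a [discrete_trajectory()] or [path_ensemble()].
#' @param split first bin label of the upper half (for 32 bins use 16).
#' @param n_bins number of bins when `x` carries no binning metadata.
#' @return the occupancy ratio (may be `Inf` printed as error, see below).
#' @export
symmetry_kappa <- function(x, split, n_bins = NULL) {
  counts <- .occupancy_counts(x, n_bins)
  split <- as.integer(split)
  if (split < 1L || split >= length(counts)) stop("split outside bin range")
  lower <- sum(counts[seq_len(split)])
  upper <- sum(counts[(split + 1L):length(counts)])
  if (upper == 0) stop("upper half unoccupied; kappa undefined")
  lower / upper
}

# Per-path kappa that returns Inf instead of erroring (for ensemble screening).
.kappa_or_inf <- function(states_row, split) {
  lower <- sum(states_row < split)
  upper <- sum(states_row >= split)
  if (upper == 0) Inf else lower / upper
}

#' Windowed squared deviation from the exponential-decay theory curve
#'
#' For photon-number trajectories, computes
#' `dn = (1/dt_window) * sum_j sum_{t in window} (n_t^j - n0 exp(-gamma t))^2`
#' where the inner sum runs over sample times in `[t_start, t_start +
#' dt_window]` and `j` over paths. Bin labels are converted to photon numbers
#' through the ensemble's bin midpoints. The per-path contributions (what the
#' reweighting acts on) are returned in attribute `per_path`.
#'
#' @param ensemble a [path_ensemble()] (binned photon-number records).
#' @param n0 initial photon number of the theory curve.
#' @param gamma decay rate of the theory curve.
#' @param t_start start of the comparison window.
#' @param dt_window window duration.
#' @param time_step sampling interval; defaults to the ensemble's `dt`.
#' @return total deviation (sum over paths), with attribute `per_path`.
#' @export
theory_deviation_dn <- function(ensemble, n0, gamma, t_start, dt_window,
                                time_step = NULL) {
  stopifnot(inherits(ensemble, "path_ensemble"))
  if (is.null(time_step)) time_step <- ensemble$dt
  Tn <- ncol(ensemble$states)
  times <- (seq_len(Tn) - 1L) * time_step
  win <- which(times >= t_start & times <= t_start + dt_window)
  if (!length(win)) stop("empty window: no sample times in [t_start, t_start + dt_window]")
  if (t_start + dt_window > max(times) + 1e-12)
    warning("window extends past the trajectory time span; truncated")
  vals <- if (!is.null(ensemble$binning)) {
    matrix(bin_midpoints(ensemble$binning)[ensemble$states + 1L],
           nrow = nrow(ensemble$states))
  } else ensemble$states + 0
  theory <- n0 * exp(-gamma * times[win])
  dev2 <- sweep(vals[, win, drop = FALSE], 2L, theory, "-")^2
  per_path <- rowSums(dev2) / dt_window
  out <- sum(per_path)
  attr(out, "per_path") <- per_path
  out
}

#' Evaluate an observable on every path of an ensemble
#'
#' Dispatches on the observable kind and returns the raw per-path values
#' (ensemble weights are ignored; weighting happens in the resampler).
#'
#' @param spec an [observable_spec()].
#' @param ensemble a [path_ensemble()].
#' @return numeric vector, one value per path. For `symmetry_kappa`, paths
#'   that never visit the upper half evaluate to `Inf` (screened out by the
#'   resampler with a diagnostic).
#' @export
evaluate_observable <- function(spec, ensemble) {
  stopifnot(inherits(spec, "observable_spec"), inherits(ensemble, "path_ensemble"))
  np <- n_paths(ensemble)
  member <- function(i) ensemble_member(ensemble, i)
  switch(spec$kind,
    nn_transition_rate = vapply(seq_len(np), function(i)
      nn_transition_rate(member(i)), numeric(1)),
    pair_transition_rate = vapply(seq_len(np), function(i)
      pair_transition_rate(member(i), spec$params$pairs), numeric(1)),
    symmetry_kappa = vapply(seq_len(np), function(i)
      .kappa_or_inf(ensemble$states[i, ], as.integer(spec$params$split)),
      numeric(1)),
    theory_deviation_dn = {
      p <- spec$params
      as.numeric(attr(theory_deviation_dn(ensemble, p$n0, p$gamma, p$t_start,
                                          p$dt_window, p$time_step), "per_path"))
    },
    custom = vapply(seq_len(np), function(i) spec$params$fn(member(i)), numeric(1)),
    stop("unknown observable kind: ", spec$kind))
}
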
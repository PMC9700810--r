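#' Exponentially tilted (reweighted) ensemble mean
#'
#' `<s>_dl = sum_k s_k exp(-dl * s_k) / sum_k exp(-dl * s_k)`, computed in
#' log space (shift by the maximum exponent) so it is stable for large
#' `|dl * s|`. This function is strictly decreasing in `dl` whenever the
#' `s_k` are not all equal (its derivative is minus the tilted variance).
#'
#' @param s_values numeric vector of per-path observable values.
#' @param delta_lambda tilt parameter.
#' @return the reweighted mean.
#' @export
reweighted_mean <- function(s_values, delta_lambda) {
  a <- -delta_lambda * s_values
  a <- a - max(a)
  w <- exp(a)
  sum(w * s_values) / sum(w)
}

#' Solve the single-constraint Maximum Caliber multiplier shift
#'
#' Finds `delta_lambda` such that the exponentially tilted ensemble average
#' of the sampled path observables equals the target:
#' `target = sum_k s_k e^{-dl s_k} / sum_k e^{-dl s_k}`. The left-hand side
#' is strictly monotone decreasing in `dl`, so a geometrically expanded
#' bracket plus [stats::uniroot()] (with a Newton polish using the analytic
#' derivative, minus the tilted variance) is guaranteed to converge whenever
#' the target lies strictly inside the open range of sampled values.
#'
#' @param s_values per-path observable values (finite).
#' @param target desired ensemble average, strictly inside
#'   `(min(s), max(s))`.
#' @param tol relative accuracy of the achieved mean (default 1e-10).
#' @return `delta_lambda` (negative when raising the average above the
#'   unweighted mean).
#' @examples
#' s <- c(rep(0, 50), rep(1, 50))
#' solve_delta_lambda(s, 1 / (1 + exp(1)))  # exactly 1
#' @export
solve_delta_lambda <- function(s_values, target, tol = 1e-10) {
  s <- as.numeric(s_values)
  if (any(!is.finite(s))) stop("s_values must be finite")
  if (!is.finite(target)) stop("target must be finite")
  if (diff(range(s)) == 0) stop("degenerate observable: all s values equal")
  if (target <= min(s) || target >= max(s))
    stop("constraint unreachable from sampled ensemble - generate more/longer paths")
  f <- function(dl) reweighted_mean(s, dl) - target
  if (abs(f(0)) <= tol * max(abs(target), 1)) return(0)
  # geometric bracket expansion; f is decreasing
  lo <- -1; hi <- 1
  scale <- max(abs(s)); if (scale > 0) { lo <- lo / scale; hi <- hi / scale }
  while (f(lo) < 0) lo <- lo * 2
  while (f(hi) > 0) hi <- hi * 2
  dl <- stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.75)$root
  # Newton polish: d<s>/d(dl) = -Var_w(s)
  for (k in 1:50) {
    a <- -dl * s; a <- a - max(a); w <- exp(a); w <- w / sum(w)
    m <- sum(w * s)
    if (abs(m - target) <= tol * max(abs(target), 1e-300)) break
    v <- sum(w * (s - m)^2)
    if (v <= 0) break
    dl <- dl + (m - target) / v
  }
  dl
}

#' Solve coupled multipliers for two or more simultaneous constraints
#'
#' Solves the system of tilted-average equations with joint weights
#' `w_k \propto exp(-sum_j dl_j s_j(k))` by damped Newton iteration with a
#' finite-difference Jacobian. Residuals below `tol` are required.
#'
#' @param s_matrix numeric matrix, `n_paths x n_constraints`.
#' @param targets one target per constraint, each strictly inside the open
#'   range of its column.
#' @param tol residual tolerance (default 1e-8).
#' @param max_iter iteration cap.
#' @return vector of `delta_lambda`, one per constraint.
#' @export
solve_multi <- function(s_matrix, targets, tol = 1e-8, max_iter = 200L) {
  s_matrix <- as.matrix(s_matrix)
  nc <- ncol(s_matrix)
  if (nc < 2L) stop("solve_multi needs >= 2 constraints; use solve_delta_lambda")
  if (length(targets) != nc) stop("one target per constraint required")
  for (j in seq_len(nc)) {
    rj <- range(s_matrix[, j])
    if (targets[j] <= rj[1] || targets[j] >= rj[2])
      stop(sprintf("target %d outside the open range of its sampled values", j))
  }
  resid <- function(dl) {
    a <- -as.vector(s_matrix %*% dl)
    a <- a - max(a)
    w <- exp(a); w <- w / sum(w)
    as.vector(crossprod(s_matrix, w)) - targets
  }
  dl <- numeric(nc)
  r <- resid(dl)
  for (it in seq_len(max_iter)) {
    if (max(abs(r)) < tol) return(dl)
    # finite-difference Jacobian
    J <- matrix(0, nc, nc)
    hstep <- pmax(1e-6, 1e-6 * abs(dl))
    for (j in seq_len(nc)) {
      dlj <- dl; dlj[j] <- dlj[j] + hstep[j]
      J[, j] <- (resid(dlj) - r) / hstep[j]
    }
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) stop("singular Jacobian in solve_multi (constraints may be ",
                            "perfectly correlated or inconsistent)")
    lam <- 1
    repeat {
      cand <- dl + lam * step
      rc <- resid(cand)
      if (sum(rc^2) < sum(r^2) || lam < 1e-10) break
      lam <- lam / 2
    }
    if (lam < 1e-10)
      stop(sprintf("solve_multi failed to reduce residuals (max residual %.3g)",
                   max(abs(r))))
    dl <- dl + lam * step
    r <- resid(dl)
  }
  if (max(abs(r)) >= tol)
    stop(sprintf("solve_multi did not converge in %d iterations (max residual %.3g)",
                 max_iter, max(abs(r))))
  dl
}

#' Normalized Maximum Caliber path weights
#'
#' `w_k \propto exp(-sum_j delta_lambda_j * s_j(Gamma_k))`, normalized to sum
#' to 1 and computed with a log-sum-exp shift for stability. Adding any
#' constant to a column of `s_matrix` leaves the weights unchanged.
#'
#' @param s_matrix per-path observable values: vector (one constraint) or
#'   `n_paths x n_constraints` matrix.
#' @param delta_lambda one multiplier shift per constraint.
#' @return normalized weight vector over paths.
#' @export
path_weights <- function(s_matrix, delta_lambda) {
  s_matrix <- as.matrix(s_matrix)
  if (ncol(s_matrix) != length(delta_lambda))
    stop("delta_lambda length must match the number of observable columns")
  a <- -as.vector(s_matrix %*% delta_lambda)
  a <- a - max(a)
  w <- exp(a)
  w / sum(w)
}

#' Effective sample size of a normalized weight vector
#' @param weights normalized nonnegative weights.
#' @return `1 / sum(w^2)`, between 1 and `length(weights)`.
#' @export
effective_sample_size <- function(weights) 1 / sum((weights / sum(weights))^2)

#' Draw a biased subsample of paths
#'
#' Selects `k` member trajectories with probability proportional to the given
#' weights, without replacement by default (avoiding duplicate training
#' sequences in the retraining step). The returned ensemble is unweighted.
#'
#' @param ensemble a [path_ensemble()].
#' @param weights per-path selection weights (need not be normalized).
#' @param k subset size (`<=` number of paths with nonzero weight when
#'   sampling without replacement).
#' @param seed RNG seed.
#' @param replace sample with replacement instead.
#' @return A [path_ensemble()] of the selected paths; the chosen indices are
#'   in attribute `indices`.
#' @export
subsample_paths <- function(ensemble, weights, k, seed = 1L, replace = FALSE) {
  stopifnot(inherits(ensemble, "path_ensemble"))
  np <- n_paths(ensemble)
  if (length(weights) != np) stop("one weight per path required")
  if (any(!is.finite(weights)) || any(weights < 0)) stop("weights must be finite and >= 0")
  k <- as.integer(k)
  if (k < 1L || k > np) stop("k must be between 1 and the ensemble size")
  if (!replace && sum(weights > 0) < k)
    stop("k exceeds the number of paths with nonzero weight")
  idx <- .with_seed(seed, sample.int(np, k, replace = replace, prob = weights))
  out <- path_ensemble(ensemble$states[idx, , drop = FALSE],
                       dt = ensemble$dt, binning = ensemble$binning)
  attr(out, "indices") <- idx
  out
}

#' Constraint target for the resampling pipeline
#'
#' @param observable an [observable_spec()].
#' @param target desired ensemble-averaged value of the observable.
#' @param tolerance relative tolerance for verification (default 0.02,
#'   i.e. 2 percent).
#' @return An object of class `constraint_target`.
#' @export
constraint_target <- function(observable, target, tolerance = 0.02) {
  stopifnot(inherits(observable, "observable_spec"))
  if (!is.finite(target)) stop("target must be finite")
  structure(list(observable = observable, target = target, tolerance = tolerance),
            class = "constraint_target")
}

.within_tol <- function(achieved, target, tolerance) {
  abs(achieved - target) <= tolerance * max(abs(target), 1e-12) +
    (target == 0) * tolerance
}

# Maximum Caliber constrains ensemble *averages*, so every constrained
# observable must be linear in the ensemble. The occupancy-symmetry ratio
# kappa is not: the mean of per-path ratios is Jensen-biased away from the
# pooled ratio when paths are short. Constraining kappa therefore goes
# through its linear equivalent, the lower-half occupancy fraction
# f = kappa / (1 + kappa); the pooled kappa of equal-length paths is exactly
# mean(f) / (1 - mean(f)). Targets and achieved values are transformed back
# for reporting.
.internal_constraints <- function(constraints) {
  lapply(constraints, function(ct) {
    sp <- ct$observable
    if (sp$kind == "symmetry_kappa") {
      split <- as.integer(sp$params$split)
      list(spec = observable_spec("custom",
                                  fn = function(traj) mean(traj$states < split),
                                  name = "lower_half_fraction"),
           target = ct$target / (1 + ct$target),
           tolerance = ct$tolerance,
           back = function(f) f / (1 - f))
    } else {
      list(spec = sp, target = ct$target, tolerance = ct$tolerance,
           back = identity)
    }
  })
}

#' Full constrained-retraining pipeline (path-sampled LSTM)
#'
#' Implements the complete workflow that turns an unconstrained generator
#' into a constraint-satisfying one: generate `n_generate` paths from the
#' model, evaluate the constrained observables on each path, solve the
#' Maximum Caliber multiplier shift(s) so that the tilted ensemble average
#' hits the target(s), draw a biased subsample of `subset_size` paths with
#' weights `exp(-sum_j dl_j s_j)`, and retrain a fresh model on the subset.
#' The subsample is re-verified before retraining: candidate draws are taken
#' until the subset mean of each observable is within tolerance of its
#' target (the draw closest to target is kept if none passes), and the
#' retrained model's own generated ensemble is verified afterwards, with a
#' warning (never silent success) if a constraint is missed.
#'
#' Paths with non-finite observable values (e.g. an occupancy ratio with an
#' empty denominator) carry no usable signal for the constraint; they are
#' excluded from the solve, given zero selection weight, and counted in the
#' diagnostics.
#'
#' A target outside the open range of the sampled values is an error by
#' default. With `boundary = "clip"` the pipeline instead degenerates to
#' selecting the `subset_size` paths nearest the target (the infinite-tilt
#' limit), which is how a boundary target such as "zero deviation from a
#' theory curve" is imposed in practice.
#'
#' @param model trained unconstrained [sequence_model].
#' @param constraints a [constraint_target()] or list of them.
#' @param n_generate paths generated from the unconstrained model.
#' @param subset_size paths retained for retraining.
#' @param length,init passed to [generate_paths()].
#' @param seed master seed; all internal streams derive from it.
#' @param retrain_config optional [model_config()] for the retrained model
#'   (defaults to the input model's config, fresh initialization).
#' @param boundary `"error"` (default) or `"clip"` for targets outside the
#'   sampled range.
#' @param max_redraws candidate subsample draws for verification.
#' @param n_retrain number of independently subsampled-and-retrained models;
#'   when `> 1` the returned `model` is a list (a deep-ensemble mixture that
#'   [generate_paths()] samples by averaging predictive distributions  —
#'   recommended for constraints on stationary populations, whose
#'   single-network estimates are exponentially sensitive to fitting noise).
#' @param ensemble optionally, a pre-generated [path_ensemble()] to resample
#'   from instead of generating `n_generate` paths internally (e.g. paths
#'   generated from several initial conditions).
#' @param n_verify paths generated from the retrained model for the final
#'   verification (0 skips it).
#' @return list with elements `model` (the retrained generator), `solution`
#'   (class `constraint_solution`: `delta_lambda`, `weights`, `achieved`,
#'   `ess`, `n_excluded`, per-path `s_values`), `subset` (the retained
#'   ensemble), `ensemble` (the full generated ensemble the subset was drawn
#'   from) and `verification` (achieved values from the retrained model).
#' @export
constrain_pipeline <- function(model, constraints, n_generate, subset_size,
                               length, init, seed = 1L,
                               retrain_config = NULL,
                               boundary = c("error", "clip"),
                               max_redraws = 100L, n_retrain = 1L,
                               ensemble = NULL, n_verify = 50L) {
  boundary <- match.arg(boundary)
  if (inherits(constraints, "constraint_target")) constraints <- list(constraints)
  stopifnot(all(vapply(constraints, inherits, logical(1), "constraint_target")))
  if (n_generate < subset_size) stop("n_generate must be >= subset_size")
  base_cfg <- if (inherits(model, "sequence_model")) model$config
              else model[[1L]]$config
  ens <- if (is.null(ensemble)) {
    generate_paths(model, n_generate, length, init, seed = .sub_seed(seed, 1))
  } else {
    stopifnot(inherits(ensemble, "path_ensemble"))
    ensemble
  }
  nC <- base::length(constraints)
  if (nC == 0L) {
    # no-op constraint: retrain on an unbiased subsample of the model's output
    sub <- subsample_paths(ens, rep(1, n_paths(ens)), subset_size,
                           seed = .sub_seed(seed, 3))
    cfg <- if (is.null(retrain_config)) base_cfg else retrain_config
    cfg$seed <- .sub_seed(seed, 4)
    new_model <- train_lstm(sub, cfg)
    return(list(model = new_model, solution = NULL, subset = sub,
                verification = NULL))
  }
  ics <- .internal_constraints(constraints)
  s_mat <- vapply(ics, function(ic) evaluate_observable(ic$spec, ens),
                  numeric(n_paths(ens)))
  s_mat <- matrix(s_mat, nrow = n_paths(ens))
  ok <- apply(is.finite(s_mat), 1L, all)
  n_excluded <- sum(!ok)
  s_ok <- s_mat[ok, , drop = FALSE]
  targets <- vapply(ics, `[[`, numeric(1), "target")
  clip_mode <- FALSE
  if (boundary == "clip") {
    rng <- apply(s_ok, 2L, range)
    clip_mode <- any(targets <= rng[1, ] | targets >= rng[2, ])
  }
  if (clip_mode) {
    # infinite-tilt limit: keep the subset_size paths closest to the target(s)
    d <- rowSums(sweep(s_ok, 2L, targets, "-")^2)
    w_ok <- as.numeric(rank(d, ties.method = "first") <= subset_size)
    delta_lambda <- ifelse(targets <= apply(s_ok, 2L, min), Inf, -Inf)
  } else {
    delta_lambda <- if (nC == 1L) solve_delta_lambda(s_ok[, 1], targets[1])
                    else solve_multi(s_ok, targets)
    w_ok <- path_weights(s_ok, delta_lambda)
  }
  weights <- numeric(nrow(s_mat)); weights[ok] <- w_ok
  weights <- weights / sum(weights)
  achieved <- as.vector(crossprod(s_mat[ok, , drop = FALSE], weights[ok] / sum(weights[ok])))
  # verified biased subsamples: redraw until the subset mean is within
  # tolerance (keeping the closest candidate otherwise); one independently
  # drawn subset per retrained model
  tols <- vapply(ics, `[[`, numeric(1), "tolerance")
  draw_verified <- function(stream) {
    best <- NULL; best_err <- Inf
    for (r in seq_len(max(1L, max_redraws))) {
      cand <- subsample_paths(ens, weights, subset_size,
                              seed = .sub_seed(seed, stream + r))
      sm <- colMeans(s_mat[attr(cand, "indices"), , drop = FALSE])
      err <- max(abs(sm - targets) / pmax(abs(targets), 1e-12))
      if (is.finite(err) && err < best_err) { best <- cand; best_err <- err }
      if (clip_mode || all(.within_tol(sm, targets, tols))) { best <- cand; break }
    }
    best
  }
  n_retrain <- max(1L, as.integer(n_retrain))
  subs <- vector("list", n_retrain)
  fits <- vector("list", n_retrain)
  for (k in seq_len(n_retrain)) {
    subs[[k]] <- draw_verified(1000 * k)
    cfg <- if (is.null(retrain_config)) base_cfg else retrain_config
    cfg$seed <- .sub_seed(seed, 2 + 7 * k)
    fits[[k]] <- train_lstm(subs[[k]], cfg)
  }
  sub <- subs[[1L]]
  new_model <- if (n_retrain == 1L) fits[[1L]] else fits
  verification <- NULL
  if (n_verify > 0L) {
    vens <- generate_paths(new_model, n_verify, length, init,
                           seed = .sub_seed(seed, 5))
    v <- vapply(ics, function(ic) {
      sv <- evaluate_observable(ic$spec, vens)
      ic$back(mean(sv[is.finite(sv)]))
    }, numeric(1))
    verification <- v
    rtargets <- vapply(constraints, `[[`, numeric(1), "target")
    for (j in seq_len(nC)) {
      if (!clip_mode && !.within_tol(v[j], rtargets[j], pmax(tols[j], 0.1)))
        warning(sprintf(
          "retrained model misses constraint %d: achieved %.4g vs target %.4g",
          j, v[j], rtargets[j]))
    }
  }
  solution <- structure(list(delta_lambda = delta_lambda, weights = weights,
                             achieved = vapply(seq_len(nC), function(j)
                               ics[[j]]$back(achieved[j]), numeric(1)),
                             targets = vapply(constraints, `[[`, numeric(1), "target"),
                             ess = effective_sample_size(weights),
                             n_excluded = n_excluded, s_values = s_mat,
                             subset_indices = attr(sub, "indices"),
                             clip_mode = clip_mode),
                        class = "constraint_solution")
  list(model = new_model, solution = solution, subset = sub,
       subsets = if (n_retrain > 1L) subs else NULL,
       ensemble = ens, verification = verification)
}

#' @export
print.constraint_solution <- function(x, ...) {
  cat("<constraint_solution>\n")
  cat("  delta_lambda:", format(x$delta_lambda, digits = 5), "\n")
  cat("  achieved:", format(x$achieved, digits = 5),
      " targets:", format(x$targets, digits = 5), "\n")
  cat(sprintf("  ess: %.1f over %d paths (%d excluded as non-finite)\n",
              x$ess, base::length(x$weights), x$n_excluded))
  invisible(x)
}
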
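#' Sample a trajectory from a Markov transition kernel
#'
#' Exact ancestral sampling: the initial state is drawn from `init` (a label
#' or a distribution; default stationary) and each subsequent state from the
#' corresponding kernel row.
#'
#' @param kernel a [transition_kernel()].
#' @param length number of samples.
#' @param init initial state label, probability vector, or `NULL` for the
#'   stationary distribution.
#' @param seed RNG seed.
#' @return A [discrete_trajectory()].
#' @export
simulate_markov <- function(kernel, length, init = NULL, seed = 1L) {
  stopifnot(inherits(kernel, "transition_kernel"))
  n <- kernel$n_states
  length <- as.integer(length)
  p0 <- if (is.null(init)) stationary_distribution(kernel)
        else if (base::length(init) == 1L) {
          v <- numeric(n); v[as.integer(init) + 1L] <- 1; v
        } else as.numeric(init) / sum(init)
  .with_seed(seed, {
    s <- integer(length)
    s[1] <- sample.int(n, 1L, prob = p0)
    # presample uniforms; invert each kernel row's CDF
    cdf <- t(apply(kernel$matrix, 1L, cumsum))
    u <- stats::runif(length - 1L)
    for (t in 2:length) {
      s[t] <- min(findInterval(u[t - 1L], cdf[s[t - 1L], ], left.open = TRUE) + 1L, n)
    }
    discrete_trajectory(s - 1L, dt = 1)
  })
}

#' Asymmetric bistable (double-well) trajectory generator
#'
#' Surrogate for a slow two-state order parameter such as the collective
#' helicity coordinate of a small peptide: a discrete-state Metropolis walk
#' on a quartic double-well profile
#' `F_i = barrier * ((2 i/(n-1) - 1)^2 - 1)^2 + asymmetry * (i < n/2)`
#' (wells at the two ends of the range, barrier in the middle; the lower-half
#' well is raised by `asymmetry`, in kT units). Detailed balance holds, so
#' long-run occupancies follow `exp(-F_i)` and the population-symmetry ratio
#' approaches `exp(-asymmetry)` (asymmetry `ln 2` gives kappa ~ 0.5). At
#' each step a move to an adjacent bin is proposed with probability
#' `diffusion` and accepted with the Metropolis rule, so the
#' nearest-neighbour transition rate is controlled by `diffusion`.
#'
#' @param n_bins number of bins (>= 4; default 32).
#' @param asymmetry free-energy offset between the two halves (kT units).
#' @param barrier barrier height of the quartic profile (kT units, > 0).
#' @param diffusion probability of proposing a move at each step (0, 1].
#' @param length number of samples.
#' @param seed RNG seed.
#' @return An object of class `double_well_spec`.
#' @export
double_well_spec <- function(n_bins = 32L, asymmetry = log(2), barrier = 2,
                             diffusion = 0.5, length = 10000L, seed = 1L) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 4L) stop("n_bins must be >= 4")
  if (!is.finite(barrier) || barrier <= 0) stop("barrier must be > 0")
  if (diffusion <= 0 || diffusion > 1) stop("diffusion must be in (0, 1]")
  structure(list(n_bins = n_bins, asymmetry = asymmetry, barrier = barrier,
                 diffusion = diffusion, length = as.integer(length),
                 seed = as.integer(seed)), class = "double_well_spec")
}

#' Discrete free-energy profile of a [double_well_spec()]
#' @param spec a [double_well_spec()].
#' @return numeric vector of `n_bins` free energies (kT units).
#' @export
double_well_potential <- function(spec) {
  stopifnot(inherits(spec, "double_well_spec"))
  i <- 0:(spec$n_bins - 1L)
  u <- 2 * i / (spec$n_bins - 1L) - 1
  spec$barrier * (u^2 - 1)^2 + spec$asymmetry * (i < spec$n_bins / 2)
}

#' Simulate the double-well Metropolis walk
#'
#' @param spec a [double_well_spec()].
#' @param init_bin starting bin (default: the global free-energy minimum).
#' @return numeric vector of bin-midpoint order-parameter values on
#'   `[-1, 1]` (discretize with `binning_spec(spec$n_bins, -1, 1)` to
#'   recover the bins exactly).
#' @export
simulate_double_well <- function(spec, init_bin = NULL) {
  stopifnot(inherits(spec, "double_well_spec"))
  FF <- double_well_potential(spec)
  n <- spec$n_bins
  if (is.null(init_bin)) init_bin <- which.min(FF) - 1L
  .with_seed(spec$seed, {
    s <- integer(spec$length)
    s[1] <- as.integer(init_bin) + 1L
    u_move <- stats::runif(spec$length - 1L)
    u_dir <- stats::runif(spec$length - 1L)
    u_acc <- stats::runif(spec$length - 1L)
    for (t in 2:spec$length) {
      cur <- s[t - 1L]
      s[t] <- cur
      if (u_move[t - 1L] < spec$diffusion) {
        prop <- cur + if (u_dir[t - 1L] < 0.5) -1L else 1L
        if (prop >= 1L && prop <= n &&
            u_acc[t - 1L] < exp(-(FF[prop] - FF[cur]))) {
          s[t] <- prop
        }
      }
    }
    mid <- bin_midpoints(binning_spec(n, -1, 1))
    mid[s]
  })
}

#' Parameters of the dissipative atom-cavity quantum-jump system
#'
#' A two-level atom coupled to a leaky single-mode cavity:
#' `H_sys = omega1 a'a + omega2 s+ s- + g (s- a' + a s+)`, with a single
#' photon-emission dissipation channel of jump operator `sqrt(gamma) a`. The
#' cavity starts with `n_photons_init` photons and the atom in its excited
#' state. In the classical regime the mean photon number decays
#' approximately as `n0 * exp(-gamma t)`.
#'
#' @param n_photons_init initial Fock level of the cavity (default 7).
#' @param omega1,omega2 cavity and atom angular frequencies (default 2 pi).
#' @param g atom-cavity coupling (default pi / 2).
#' @param gamma cavity dissipation rate (>= 0).
#' @param t_max total simulated time.
#' @param dt integration step.
#' @param sample_dt interval between recorded samples.
#' @param hilbert_cutoff number of photon levels kept (Fock states
#'   `0 .. hilbert_cutoff - 1`; must exceed `n_photons_init`). With the atom
#'   this gives a `2 * hilbert_cutoff`-dimensional Hilbert space.
#' @param seed RNG seed.
#' @return An object of class `quantum_jump_spec`.
#' @export
quantum_jump_spec <- function(n_photons_init = 7L, omega1 = 2 * pi,
                              omega2 = 2 * pi, g = pi / 2, gamma = 0.1,
                              t_max = 10, dt = 0.005, sample_dt = 0.1,
                              hilbert_cutoff = 8L, seed = 1L) {
  hilbert_cutoff <- as.integer(hilbert_cutoff)
  n_photons_init <- as.integer(n_photons_init)
  if (gamma < 0) stop("gamma must be >= 0")
  if (hilbert_cutoff <= n_photons_init)
    stop("hilbert_cutoff must exceed n_photons_init")
  if (dt <= 0 || sample_dt < dt || t_max <= 0) stop("invalid time parameters")
  structure(list(n_photons_init = n_photons_init, omega1 = omega1,
                 omega2 = omega2, g = g, gamma = gamma, t_max = t_max,
                 dt = dt, sample_dt = sample_dt,
                 hilbert_cutoff = hilbert_cutoff, seed = as.integer(seed)),
            class = "quantum_jump_spec")
}

# Operators on the cavity (tensor) atom product space, photon index fastest.
.qj_operators <- function(spec) {
  nc <- spec$hilbert_cutoff
  a1 <- matrix(0 + 0i, nc, nc)
  a1[cbind(seq_len(nc - 1L), seq_len(nc - 1L) + 1L)] <- sqrt(seq_len(nc - 1L))
  id_c <- diag(nc) + 0i
  id_a <- diag(2) + 0i
  sm <- matrix(c(0, 1, 0, 0), 2, 2) + 0i  # |down><up| with basis (up, down)
  a <- kronecker(id_a, a1)
  sm_full <- kronecker(sm, id_c)
  nop <- Conj(t(a)) %*% a
  sz <- Conj(t(sm_full)) %*% sm_full
  H <- spec$omega1 * nop + spec$omega2 * sz +
    spec$g * (sm_full %*% Conj(t(a)) + a %*% Conj(t(sm_full)))
  list(a = a, nop = nop, sp_sm = sz, H = H, dim = 2L * nc)
}

# Initial state |n0> (cavity) x |up> (atom)
.qj_init_state <- function(spec, ops) {
  psi <- rep(0 + 0i, ops$dim)
  # atom "up" is the first atomic basis vector; photon index fastest
  psi[spec$n_photons_init + 1L] <- 1 + 0i
  psi
}

#' Monte Carlo wavefunction (quantum-jump) trajectories of the photon number
#'
#' Stochastic unravelling of the Lindblad dynamics: each trajectory evolves
#' under the non-Hermitian effective Hamiltonian
#' `H_eff = H_sys - (i gamma / 2) a'a` (applied through its exact matrix
#' exponential per fixed step `dt`, computed once) with decaying norm; when
#' the squared norm falls below a uniform random threshold the photon-loss
#' jump `a` is applied, the state renormalized and the threshold redrawn.
#' The cavity photon-number expectation is recorded every `sample_dt`.
#'
#' @param spec a [quantum_jump_spec()].
#' @param n_paths number of trajectories.
#' @param binning [binning_spec()] used to discretize the records; default 20
#'   uniform bins on `[0, n_photons_init]`. Use `discretize = FALSE` to get
#'   the raw expectation records instead.
#' @param discretize return a binned [path_ensemble()] (default) or the raw
#'   `n_paths x n_times` matrix of photon-number expectations.
#' @return A [path_ensemble()] with the raw records in attribute `n_expect`
#'   and sample times in attribute `times`, or the raw matrix itself.
#' @export
simulate_quantum_jump <- function(spec, n_paths, binning = NULL,
                                  discretize = TRUE) {
  stopifnot(inherits(spec, "quantum_jump_spec"))
  n_paths <- as.integer(n_paths)
  if (n_paths < 1L) stop("n_paths must be positive")
  ops <- .qj_operators(spec)
  H_eff <- ops$H - (1i * spec$gamma / 2) * ops$nop
  # exact one-step propagator of the non-Hermitian evolution
  eg <- eigen(-1i * H_eff * spec$dt)
  U <- eg$vectors %*% diag(exp(eg$values)) %*% solve(eg$vectors)
  n_steps <- round(spec$t_max / spec$dt)
  rec_every <- round(spec$sample_dt / spec$dt)
  times <- seq(0, by = spec$sample_dt, length.out = n_steps %/% rec_every + 1L)
  if (spec$gamma * spec$n_photons_init * spec$dt >= 0.1)
    stop("dt too large for the jump unravelling: gamma * <n> * dt must be < 0.1")
  .with_seed(spec$seed, {
    Psi <- matrix(0 + 0i, ops$dim, n_paths)
    Psi[spec$n_photons_init + 1L, ] <- 1 + 0i
    thresh <- stats::runif(n_paths)
    rec <- matrix(0, n_paths, length(times))
    nexp <- function(P) {
      nr <- colSums(Mod(P)^2)
      Re(colSums(Conj(P) * (ops$nop %*% P))) / nr
    }
    rec[, 1] <- nexp(Psi)
    ri <- 1L
    for (st in seq_len(n_steps)) {
      Psi <- U %*% Psi
      nrm2 <- colSums(Mod(Psi)^2)
      jump <- which(nrm2 < thresh)
      if (length(jump)) {
        Pj <- ops$a %*% Psi[, jump, drop = FALSE]
        nj <- sqrt(colSums(Mod(Pj)^2))
        nj[nj == 0] <- 1  # vacuum cannot jump; state unchanged below
        Pj <- sweep(Pj, 2L, nj, "/")
        zero <- colSums(Mod(Pj)^2) == 0
        if (any(zero)) {
          # renormalize original state instead (no photon to emit)
          Po <- Psi[, jump[zero], drop = FALSE]
          Pj[, zero] <- sweep(Po, 2L, sqrt(colSums(Mod(Po)^2)), "/")
        }
        Psi[, jump] <- Pj
        thresh[jump] <- stats::runif(length(jump))
      }
      if (st %% rec_every == 0L) {
        ri <- ri + 1L
        rec[, ri] <- nexp(Psi)
      }
    }
    if (!discretize) {
      attr(rec, "times") <- times
      return(rec)
    }
    if (is.null(binning)) binning <- binning_spec(20L, 0, spec$n_photons_init)
    states <- matrix(
      pmin(pmax(findInterval(rec, binning$edges), 1L), binning$n_bins) - 1L,
      nrow = n_paths)
    out <- path_ensemble(states, dt = spec$sample_dt, binning = binning)
    attr(out, "n_expect") <- rec
    attr(out, "times") <- times
    out
  })
}

#' Dense Lindblad-master-equation reference for the mean photon number
#'
#' Deterministic integration of
#' `drho/dt = -i [H, rho] + gamma (a rho a' - (a'a rho + rho a'a)/2)` on the
#' truncated product space, using the complex ODE integrator
#' [deSolve::zvode()]. Returns `Tr(rho_t a'a)` at the sample times. Trace
#' preservation is verified to 1e-8 (error if drifted beyond 1e-6);
#' hermiticity and positivity of the final density matrix are checked.
#'
#' @param spec a [quantum_jump_spec()].
#' @param times sample times (default `seq(0, t_max, by = sample_dt)`).
#' @return numeric vector of mean photon numbers, with attributes `times`
#'   and `trace_error`.
#' @export
lindblad_mean <- function(spec, times = NULL) {
  stopifnot(inherits(spec, "quantum_jump_spec"))
  ops <- .qj_operators(spec)
  d <- ops$dim
  if (d > 64L) stop("Hilbert dimension above 64; reduce hilbert_cutoff")
  if (is.null(times)) times <- seq(0, spec$t_max, by = spec$sample_dt)
  H <- ops$H; a <- ops$a; ad <- Conj(t(a)); nop <- ops$nop
  gam <- spec$gamma
  rhs <- function(t, y, parms) {
    rho <- matrix(y, d, d)
    drho <- -1i * (H %*% rho - rho %*% H) +
      gam * (a %*% rho %*% ad - 0.5 * (nop %*% rho + rho %*% nop))
    list(as.vector(drho))
  }
  psi0 <- .qj_init_state(spec, ops)
  rho0 <- psi0 %*% Conj(t(psi0))
  sol <- deSolve::zvode(y = as.vector(rho0), times = times, func = rhs,
                        parms = NULL, atol = 1e-10, rtol = 1e-8)
  nmean <- numeric(length(times))
  trace_err <- 0
  for (i in seq_along(times)) {
    rho <- matrix(sol[i, -1], d, d)
    tr <- Re(sum(diag(rho)))
    trace_err <- max(trace_err, abs(tr - 1))
    nmean[i] <- Re(sum(diag(nop %*% rho))) / tr
  }
  if (trace_err > 1e-6)
    stop(sprintf("trace drift %.2g > 1e-6: reduce dt / tighten tolerances", trace_err))
  rho_T <- matrix(sol[length(times), -1], d, d)
  herm_err <- max(Mod(rho_T - Conj(t(rho_T))))
  min_eig <- min(Re(eigen((rho_T + Conj(t(rho_T))) / 2,
                          only.values = TRUE)$values))
  if (herm_err > 1e-6 || min_eig < -1e-8)
    warning(sprintf("density matrix quality: hermiticity error %.2g, min eigenvalue %.2g",
                    herm_err, min_eig))
  attr(nmean, "times") <- times
  attr(nmean, "trace_error") <- trace_err
  nmean
}
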
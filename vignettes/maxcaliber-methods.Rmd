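---
title: "Constraining recurrent generative models of molecular time series with Maximum Caliber"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraining recurrent generative models of molecular time series with Maximum Caliber}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A single molecular dynamics trajectory, a photon-counting record, or any other
one-dimensional time series is a *sample* from an underlying path ensemble.
A recurrent generative model trained on it can produce arbitrarily many
synthetic replicas, but it reproduces the sample's defects along with its
physics: a too-short trajectory that over-populates one metastable state
yields a generator with the same population bias; a record taken at one
dissipation rate cannot anticipate another.

`maxcaliber` implements the path-sampling remedy. The generator is an
embedding + LSTM + softmax network over discretized states, so the
probability it assigns to an entire trajectory
\(\Gamma = (x^{(0)}, \dots, x^{(T)})\) factorizes autoregressively,
\(P_\Gamma = \prod_t \hat{y}^{(t)}[x^{(t+1)}]\). Prior knowledge enters as
constraints on ensemble averages of path functionals \(s(\Gamma)\) —
a transition rate, a population ratio, a deviation from a theory curve.
The Maximum Caliber principle (the dynamical analogue of Maximum Entropy)
says the minimally perturbed ensemble with the corrected average
\(\bar{s}^{B}\) is an exponential tilt of the original one:

\[
P^{B}_\Gamma \propto e^{-\Delta\lambda\, s(\Gamma)}\, P^{A}_\Gamma ,
\qquad
\bar{s}^{B} \;=\;
\frac{\sum_{k} s(\Gamma_k)\, e^{-\Delta\lambda\, s(\Gamma_k)}}
     {\sum_{k} e^{-\Delta\lambda\, s(\Gamma_k)}} .
\]

The workflow (`constrain_pipeline()`) is therefore: generate many paths from
the unconstrained model, evaluate \(s\) on each, solve the tilted-average
equation for \(\Delta\lambda\), draw a biased subsample with weights
\(\propto e^{-\Delta\lambda s}\), and retrain a fresh generator on the
subsample. The retrained model — the *path-sampled* (ps-) generator — samples
the constrained ensemble directly; no constraint term ever enters the loss.

## The sequence model

States are 0-based integer bins (`binning_spec()`, `discretize()`; half-open
bins with boundary clamping, so the map is deterministic, monotone and drops
no samples). The network is the textbook LSTM cell: one-hot states are
embedded (`embed_dim`, default 8), passed through `n_layers` (default 1)
recurrent layers of `hidden_dim` units (default 64), and a dense softmax
head emits the next-state distribution. Training minimizes next-state
cross-entropy, whose optimum is the true conditional distribution of the
data-generating process; that identity is what licenses reading the softmax
output as a path probability.

Choices the training data does not dictate, fixed as defaults:

* **Windows.** Contiguous overlapping windows of `batch_len` samples
  (stride half a window), hidden state reset at each window start. Window
  length bounds the temporal memory the model can exploit; 20 suffices for
  Markov-like data, ~100 is used for the non-Markovian photon records.
* **Optimizer.** Adam at a fixed learning rate of 3e-3 with global-norm
  gradient clipping at 5. At desk-scale epoch budgets (tens of passes over
  1e4–1e5 samples) a 1e-3 rate demonstrably underfits — a three-state
  kernel is still ~0.3 off after 10 epochs, versus counting-level accuracy
  (~0.02) at 3e-3 in 20 epochs.
* **Sampling temperature is 1 and generation is always multinomial**, never
  argmax: anything else would distort the path probability and with it the
  validity of the reweighting identity.
* **Epochs as regularizer.** Long training sharpens conditional
  probabilities toward the idiosyncrasies of the finite sample; for
  observables that depend exponentially on transition-rate ratios (well
  populations, below) this *amplifies* sampling error. The defaults
  (15–25 epochs) are an early-stopping compromise, the same reasoning
  Markov-state-model practitioners use when regularizing estimated kernels.

## Solving the multiplier

`solve_delta_lambda()` exploits that the tilted mean is strictly decreasing
in \(\Delta\lambda\) (its derivative is minus the tilted variance), so a
geometrically expanded bracket plus `uniroot()`, then a Newton polish with
the analytic derivative, is guaranteed once the target lies strictly inside
the open range of sampled values — outside it the constraint is simply not
reachable from the sample and the function says so. All weight computations
run in log space (max-shifted exponentials) so large \(|\Delta\lambda\,s|\)
cannot overflow. Multiple simultaneous constraints (`solve_multi()`) use
damped Newton with a finite-difference Jacobian on the coupled tilted-average
residuals.

Sign convention: raising an observable above its unconstrained mean requires
\(\Delta\lambda < 0\). For the three-state reference kernel shipped with the
package (unconstrained pair rate \(\approx 0.089\), target 0.13 over 200
sampled paths) the solved multiplier is of order \(-30\) to \(-60\),
matching the magnitude reported for this experiment in the literature this
method reproduces.

### Constraints that are not ensemble-linear

Maximum Caliber constrains ensemble *averages*. The population-symmetry
ratio \(\kappa = \sum_{i<16} P_i / \sum_{i \ge 16} P_i\) is a ratio of
averages, and with short paths the mean of per-path ratios is Jensen-biased
away from the pooled ratio (per-path \(\kappa\) is strongly right-skewed
when a path can spend most of its time on one side). `constrain_pipeline()`
therefore constrains the *linear* equivalent, the lower-half occupancy
fraction \(f = \kappa/(1+\kappa)\), and transforms back for reporting: the
pooled \(\kappa\) of equal-length paths is exactly \(\bar f/(1-\bar f)\).
In the long-path limit the two recipes coincide. Per-path values that are
non-finite (a path that never visits the upper half has undefined ratio)
carry no information about the ratio and are excluded from the solve with a
diagnostic count.

A target at the boundary of the attainable range — "zero deviation from the
theory curve" — has no finite multiplier. With `boundary = "clip"` the
pipeline takes the infinite-tilt limit: it keeps the `subset_size` paths
closest to the target, which is what the exponential weights converge to.

### Subsampling and verification

Subsampling is without replacement by default (duplicate training sequences
add nothing and skew the retraining set); with-replacement is available for
very degenerate weights. Because a 10-of-200 draw is itself noisy, the
pipeline *verifies before retraining*: candidate subsets are drawn until the
subset mean of each constrained observable is within tolerance (default 2%)
of its target, keeping the best candidate otherwise — i.e. the multiplier is
solved once, but the realized subset is required to actually carry the
constraint, mirroring how the resampling is described in the source
experiments. After retraining, the new model's own generated ensemble is
checked once more and a warning (never a silent success) reports a missed
constraint.

## The analytic Markov oracle

For Markov dynamics everything above has closed forms, which is what makes
the three-state system the package's primary validation target:
the exact path probability is \(p_{i_0}\prod_k p_{i_k i_{k+1}}\)
(`enumerate_paths()` for exhaustive small-\(T\) enumeration), and tilting
pairwise transition counts multiplies each counted kernel entry by
\(e^{-\Delta\lambda_{\mathrm{eff}}}\) with per-row renormalization
(`reweight_kernel()`). When the constrained observable is a per-*step* rate,
the exponent per event is \(\Delta\lambda / L_{\mathrm{traj}}\)
(`exponent = "per_step"`); for per-event constraints it is
\(\Delta\lambda\) itself. Row renormalization is the leading-order
prediction: the exact tilted chain also carries a Perron-eigenvector
correction that grows with the tilt, visible only at counting precision far
beyond what the subsampled ensembles here resolve. `L_traj` is interpreted
as the number of *steps* (\(T-1\)), so a path that transitions at every step
has rate exactly 1.

Stationary distributions are dense linear solves, spectra come from
`eigen()` with implied timescales \(-\Delta t/\ln|\lambda_i|\), and
free-energy profiles are \(-k_BT\ln P_i\) relative to their minimum.

## What the synthetic generators emulate

Every experiment in the package runs on data from one of three generators,
all seed-deterministic with documented update rules.

**Three-state chain.** `three_state_kernel()` has two long-lived end states
and a short-lived intermediate, calibrated so the stationary
nearest-neighbour pair rate is ~0.089 transitions/step, the regime of the
benchmark it reproduces. `simulate_markov()` is exact ancestral sampling.

**Asymmetric double well.** A Metropolis walk on a quartic two-well profile
over 32 bins, `F_i = barrier * ((2i/(n-1) - 1)^2 - 1)^2 + asymmetry * (i <
n/2)`, stands in for a slow conformational coordinate such as the collective
helicity of a small achiral peptide, whose left/right populations should be
equal but are not in a short sample. Detailed balance holds by construction,
so the long-run occupancies are Boltzmann and the population ratio is
analytically \(e^{-\Delta F}\) (asymmetry \(\ln 2\) gives \(\kappa \approx
0.5\)). Defaults — barrier 1 kT, diffusion 0.45 — were calibrated so that
(i) the nearest-neighbour rate is ~0.41, matching the ~0.4 of the reference
peptide data, and (ii) a 6e4-step trajectory contains a few tens of
well-to-well transitions, the same crossing statistics per trajectory as the
reference 20–100 ns simulations. What this generator does *not* emulate:
multi-pathway transitions, non-Markovian memory from projected orthogonal
degrees of freedom, and force-field-specific anharmonicity; passing tests
here show the method's mechanics, not its behaviour on all-atom data.

**Dissipative atom–cavity system.** A two-level atom coupled to a leaky
single-mode cavity, \(H_{\mathrm{sys}} = \omega_1 a^\dagger a + \omega_2
\sigma_+\sigma_- + g(\sigma_- a^\dagger + a\sigma_+)\) with the single jump
operator \(\sqrt{\gamma}\,a\), started from seven photons and an excited
atom. `simulate_quantum_jump()` is a Monte Carlo wavefunction unravelling:
deterministic evolution under \(H_{\mathrm{sys}} - \tfrac{i\gamma}{2}
a^\dagger a\) with decaying norm, a photon-loss jump when the squared norm
crosses a uniform threshold. Because the effective Hamiltonian is
time-independent, the per-step propagator is applied through its *exact*
matrix exponential (one eigendecomposition up front) rather than a
first-order Euler factor — same fixed `dt` (0.005), strictly smaller
integration error, identical cost per step. The mean-field reference
`lindblad_mean()` integrates the full master equation with the complex ODE
solver `deSolve::zvode()`, monitoring trace (error beyond 1e-6 aborts),
hermiticity and positivity. The photon-number expectation is recorded every
0.1 time units and discretized into 20 bins on `[0, 7]`. The Hilbert space
keeps 8 photon levels x 2 atomic levels = 16 dimensions (configurable); the
truncation is shared by the jump simulator and the Lindblad reference, so
oracle comparisons are truncation-consistent. In the classical regime the
mean photon number decays as \(n_0 e^{-\gamma t}\), which is the theory
curve the \(\delta n\) constraint uses.

## Desk-scale experiment design

The validation experiments (test suite and `scripts/acceptance.R`) run the
full workflow at sizes a laptop CPU completes in minutes; the sizes are part
of the experimental design, stated here once:

* **Three-state rate constraint**: training series 1e4 steps; 200 generated
  paths of 150 samples; subset 10; target pair rate 0.13. Short generated
  paths are deliberate — the per-path rate spread shrinks as
  \(L^{-1/2}\), and the target must stay inside the sampled range.
* **Double-well symmetry constraint** (`restore_symmetry()`): training
  series 1e5 steps (long enough that the sample's own \(\kappa\) sits near
  its 0.5 equilibrium); 150 candidate paths of 30000 samples continued
  autoregressively from the training trajectory's starting well, each
  path's initial transient discarded before the constraint is evaluated
  (all candidates start in the favoured well, so whole-path occupancy
  under-reports the equilibrium fraction — solving on the path bodies
  removes a systematic tilt of order the transient fraction); subset 10;
  target \(\kappa = 1\). Two further hardening measures, each motivated by
  a diagnosed desk-scale failure mode:
  (i) *stationary-ratio stability of a single network.* The cross-entropy
  loss converges to a flat plateau whose points differ by factor-e
  stationary ratios, so a constant learning rate leaves \(\kappa\)
  bouncing epoch to epoch; training here uses the step-decayed rate plus
  weight averaging (`lr_schedule = "step"`, `swa = TRUE`), after which a
  single network's \(\kappa\) tracks its training data's.
  (ii) *mixture generation.* The unconstrained sampler averages the
  predictive distributions of 2 independently trained networks and the
  path-sampled generator those of 3 networks retrained on independently
  drawn verified subsets — the probability-space counterpart of the
  repeated-independent-training averaging reported for the reference
  experiment; it cancels residual fitting noise before it compounds
  exponentially into populations.
  A third candidate measure — a corrective resampling round that re-targets
  by the measured miss, as in iterative Boltzmann inversion — is
  implemented (`refine = TRUE`) but off by default: in validation its
  round-to-round variability exceeded the systematic shift it corrects,
  because a subset tilted to an off-balance target reintroduces the very
  selection pathologies the balanced target avoids.
  \(\kappa\) is measured on ~2e6 pooled occupancy samples from paths
  started half in each well with a burn-in discarded: symmetric inits
  cancel the initialization transient, and the sample size matters because
  the information about a population ratio is carried by well-to-well
  crossings, not by raw samples. Even so, the residual run-to-run scatter
  of the restored ratio is of order 10–20%, the honest desk-scale
  resolution of this experiment.
* **Double-well kinetic constraint**: targets 0.38 and 0.42 on the
  nearest-neighbour rate from 800 paths of 700 samples; mean inter-well
  transition times measured entry-to-entry between the two outer
  macrostates on long generated paths, averaged over repeats. Only the
  *ordering* of the two transition times is a stable desk-scale observable.
* **Photon-record constraint**: 500 training records at \(\gamma = 0.1\);
  the \(\delta n\) functional (squared deviation from the \(\gamma = 0.2\)
  decay curve over the classical window \(t \in (5, 7)\), per unit window)
  is driven to its boundary target 0 via the clip rule, selecting the 20
  closest paths of 2000 for retraining.

## Degenerate inputs, ties, tolerances

Discretization clamps out-of-range values and reports how many (attribute
`clamped`); non-finite inputs error with their index. Kernel rows must sum
to 1 within 1e-10; kernel estimation refuses states never seen as a source
unless `unvisited = "uniform"` is requested explicitly. The multiplier solve
demands the target strictly inside the open sampled range and reports the
achieved mean to 1e-10 relative; weights are compared against the naive
formula in tests to 1e-12 in the safe regime. Seeds: every stochastic
function takes one, restores the caller's RNG state, and derives
per-stage child streams from a single master seed in the pipeline, so a full
run is bit-reproducible.

## Known limitations

* A single 1-D order parameter; no multivariate observables.
* The LSTM is the only architecture; the reweighting itself is
  architecture-agnostic and would wrap any autoregressive sampler.
* Tilted-kernel prediction uses row renormalization (leading order in the
  tilt), not the exact eigenvector-corrected transform.
* Equilibrium-population constraints at desk scale inherit the exponential
  sensitivity discussed above: a single retrained network's population
  ratio scatters by tens of percent; generate from a mixture of independent
  retrainings when you need better.
* The quantum generator records expectation values of the photon number, not
  projective measurement outcomes (an option records jump counts instead);
  its Hilbert space is truncated, consistently with its oracle.
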
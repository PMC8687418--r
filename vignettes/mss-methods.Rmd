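---
title: "Multiple-shooting inference for stochastic reaction networks: models, approximations and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple-shooting inference for stochastic reaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mssinfer)
```

## The estimation problem

A mass-action reaction network over species $X_1,\dots,X_D$ with $r$
reactions is summarised by its stoichiometric matrix $S$ (species × net
change per reaction) and hazard vector $v(x,\theta)$, with
$v_k = \theta_k \prod_i x_i^{q_{ik}}$.  Counts evolve as a continuous-time
discrete-state Markov jump process; `ssa_simulate()` realises it exactly
with the Gillespie direct method.  Data are counts $\nu_0,\dots,\nu_n$
recorded at times $t_0 < \dots < t_n$, and the goal is the kinetic parameter
vector $\theta$.

By the Markov property the likelihood factorises into one-step transition
probabilities $p(\nu_i \mid \nu_{i-1}, \Delta_i, \theta)$.  These are not
available in closed form for general networks, and computing them by
simulation or by solving the master equation is expensive.  The estimator
implemented here replaces each of them with a Gaussian:

* **mean** — the reaction-rate ODE $\dot x = S\,v(x,\theta)$ solved over
  the single interval $[t_{i-1}, t_i]$, restarted at the previous *datum*
  $\nu_{i-1}$ (the multiple-shooting step);
* **covariance** — the linear noise approximation on the same interval,
  $\dot\Sigma = J\Sigma + \Sigma J^\top + \Omega^{-1} D$ with $\Sigma(0)=0$,
  $J = S\,\partial v/\partial x$ and
  $D_{ij} = \sum_k S_{ik}S_{jk}v_k$, both evaluated along the evolving
  interval mean $x(t)$.

Minimising
$F(\nu,\theta) = -\sum_i \log \phi(\nu_i;\, x(\Delta_i;\theta,\nu_{i-1}),\,
\Sigma(\Delta_i;\theta))$
gives a completely deterministic objective — statistically, a Gaussian
non-linear first-order autoregression — that gradient-based optimisers
handle directly (`mss_fit()`).  Because the approximation is only asked to
hold *between* consecutive measurements, not over the whole horizon, it
tolerates strongly stochastic dynamics (extinctions, noise-induced
behaviour) that defeat a global Gaussian approximation.  Each evaluation
costs one integration of $D + D(D+1)/2$ equations per interval.

The interval-wise Jacobian argument deserves a note: one could freeze $J$
and $D$ at the interval's endpoint mean instead of evaluating them along
$x(t)$.  Both appear in the literature on short-interval moment expansions;
the time-varying form is implemented because it is the standard
first-order system-size expansion and is exact for linear hazards either
way.  For the interval lengths in the benchmark designs the difference is
far below the statistical error.

### Partial observation

When only species in an index set $O$ are measured, the shooting start of
each interval combines the observed data with *propagated* hidden
components: the hidden part of the previous interval's ODE endpoint.  The
density is evaluated on the observed marginal (mean block, covariance
block).  The hidden state at $t_0$ either is known (and held fixed,
`estimate_hidden = FALSE`) or joins the optimisation vector.  This is a
deliberately primitive state estimate — no conditioning on the LNA
cross-covariance, no smoothing — chosen to keep intervals independent and
the objective simple; richer state estimation would blur the one-interval
locality that motivates the construction.

### Measurement noise

Independent Gaussian measurement noise with covariance $\Sigma_{meas}$
inflates each observed-block covariance to
$\Sigma^{obs}+\Sigma_{meas}$; the noisy datum itself still serves as the
shooting start (a simple state estimate).  With `estimate_sigma = TRUE` a
scalar noise standard deviation is estimated jointly
($\Sigma_{meas}=\sigma^2 I$).  Because the *conditioning point* is noisy
but treated as exact, this variant suffers errors-in-variables attenuation
when the per-interval intrinsic variance is small relative to
$\sigma^2$: dynamics speed up and $\sigma$ shrinks to compensate.  The
effect is visible in the benchmark gene-network design as inflated
degradation/translation rates at larger $\sigma$, and it makes
slowly-relaxing scalar models at coarse sampling a poor setting for joint
$\sigma$ estimation.  The package documents rather than hides this: the
residual diagnostic below flags such fits.

### Checking the approximation

For each interval the standardised residual
$r_i = (\Sigma^{obs}+\Sigma_{meas})^{-1/2}(x(\Delta_i) - \nu_i)$
is the Gaussian "random number" that would have generated the datum, so
under the approximation the $n$ residuals are i.i.d. $N(0, I)$
(`approximation_residuals()`); `normality_check()` applies a per-component
Kolmogorov–Smirnov test.  The symmetric (eigendecomposition) matrix square
root is used, which is covariant under species reordering; any fixed root
convention yields $N(0,I)$ under the null.  The check is *supportive*, not
decisive: a failing check means the covariance weights are off, but since
the covariance enters only as a weighting factor, estimates frequently
remain accurate (the constant-variance predecessor objective works at all
only because of this).  Reported verdicts are worded accordingly.

## Built-in benchmark models

* **Immigration–death** — influx at $\theta_1$, per-capita decay
  $\theta_2 x$; $S = (1, -1)$.  Its master equation is solvable: the count
  after $\Delta t$ from $n_0$ is Binomial$(n_0, e^{-\theta_2\Delta t})$
  survivors plus Poisson immigrants.  `id_transition_pmf()` /
  `id_mle()` expose this as an oracle and a reference estimator.  Because
  the hazards are linear, the LNA conditional mean and variance are
  *exact* here — the package's central correctness anchor, tested to
  integrator tolerance.
* **Prokaryotic auto-regulatory gene network** — a promoter reversibly
  sequestered by a protein dimer, with transcription, translation,
  dimerisation and decay (8 parameters).  The moiety
  DNA + DNA·P2 = DNA$_t$ is conserved, which would make the full
  5-species LNA covariance singular; the model is therefore built on the 4
  independent species with DNA·P2 eliminated through the total
  (`full_states()` reconstructs it).  The dimerisation hazard is
  $\theta_5 P^2$, matching the model's rate equations, so that exact
  simulation, ODE mean and LNA share one kinetic convention; the
  combinatorial kernel $\theta_5 P(P-1)/2$ is available per reaction
  (`combinatorial_dimer = TRUE`) but off by default.
* **Lotka–Volterra** — prey birth, predation, predator death;
  the standard stochastic oscillator whose realisations can die out or
  explode within a finite horizon, qualitatively unlike the deterministic
  cycle.  `classify_trajectory()` labels realisations
  (`die_out` = all species zero at the horizon's end; `explode` = any
  count above $10^4$ or the event-ceiling hit; thresholds configurable —
  the qualitative trichotomy is standard, the exact thresholds are a
  package choice).

The volume is fixed at $\Omega = 1$ by default so that counts and
concentrations coincide; it is a plain field on the network object.

## Numerical choices

* **Integration.** Moment systems are integrated with `deSolve` (`lsoda`
  by default), the network-specific right-hand side compiled in C.
  Defaults `rtol = 1e-8`, `atol = 1e-10`, exposed everywhere.  A full
  multiple-shooting pass is one solver call: on an equidistant, fully
  observed grid all intervals are integrated simultaneously as independent
  stacked blocks (non-stiff Adams, avoiding the stacked system's dense
  Jacobian); otherwise the re-initialisation at each measurement is
  implemented with solver events, and pre-reset moments are read at
  $t_i - \varepsilon$ ($\varepsilon = 10^{-6}\min_i\Delta_i$) via dense
  output.  Single-interval quantities (`lna_moments()`) integrate to the
  exact endpoint.
* **Covariance hygiene.** Each covariance block is symmetrised; if its
  smallest eigenvalue falls below $10^{-8}\max(1,\mathrm{tr}\Sigma/D)$ a
  jitter of that size is added.  The floor (rather than a strictly
  negative-eigenvalue trigger) covers die-out intervals, where every
  hazard — and hence the entire LNA covariance — vanishes and the
  transition is deterministic; such intervals then contribute a
  $\theta$-independent constant, leaving estimates untouched.
* **Optimisation.** `stats::optim(method = "BFGS")` on $\log\theta$
  (and $\log$ hidden states, $\log\sigma$), finite-difference gradients,
  `reltol = 1e-10`, at most 300 iterations.  Failed or absurd evaluations
  (moment integration failure, $|\log\theta| > \log 10^6$) return a smooth
  penalty $10^9(1+\overline{\log\theta^2})$ sloping back towards moderate
  parameters, so line searches recover rather than stall on a flat cliff.
  A box (default $[10^{-6}, 100]$ per parameter) acts as an *acceptance
  region*: a fit counts as converged only if the optimiser succeeded and
  the estimate is strictly inside the box (relative tolerance $10^{-6}$).
  A bound-constrained optimiser was tried first and rejected: its
  generalised Cauchy step stalls at the first iterate when penalty cliffs
  sit on the box boundary, whereas the unconstrained search with post-hoc
  acceptance matches how the benchmark studies actually treat their
  $[0,100]^8$ region.
* **Rounding in approximate simulation.** `lna_simulate()` rounds each
  Gaussian draw to the nearest integer and clamps at zero (negativity
  handling is a package choice; rounding alone would occasionally produce
  negative counts).  The raw, unrounded draws (`round = FALSE`) are what
  the residual diagnostic is exact for.
* **Tie-breaking in ranking.** To rank an external point estimate among
  replicate estimates, a multi-parameter estimate is scalarised as the
  mean of componentwise relative errors — the same structure as the
  average relative error statistic; how to scalarise is genuinely open,
  and this choice is stated prominently in `rank_external()`'s
  documentation.  Ties favour the external estimate.

## The synthetic-data generator and what the tests show

All pseudo-data come from the exact Gillespie sampler (`ssa_simulate()`,
direct method — no tau-leaping, since exactness is the point of a
ground-truth generator), with optional i.i.d. Gaussian measurement noise.
Replicate $i$ of a study derives everything (trajectory, noise, the
optimiser start drawn as truth $\times\,U[0.5,2]$ per component) from seed
$\texttt{base\_seed}+i$, so single replicates re-run in isolation.
Study defaults mirror the benchmark designs: immigration–death started at
its deterministic steady state $\theta_1/\theta_2$; the gene network from
(DNA, P2, mRNA, P) = (6, 6, 8, 25) with DNA$_t \in \{2, 10\}$; the
predator–prey system from (71, 79) with
$\theta^{(0)} = (0.5, 0.0025, 0.3)$.

This emulates intrinsic demographic stochasticity and additive measurement
error.  It does not emulate extrinsic parameter variability between cells,
non-Gaussian or multiplicative measurement error, time-varying rates, or
model misspecification — so passing tests certify the estimator under *its
own* generating assumptions (plus exact jump-process noise), not
robustness to a wrong model.

The replicated studies in the test suite use the benchmark problem sizes
(100 replicates for the immigration–death and predator–prey designs at
101×10 and 40×1; 10 replicates for the 500-point gene-network design, whose
per-fit cost is ~15 s; the full 100-replicate gene-network table is a
supported but long run).  Residual-calibration checks use 200 simulated
series of 21 points.

## Known limitations

* Validity inherits the LNA's assumptions per interval; very sparse events
  per interval with near-zero counts (e.g. influx rate unobservably small)
  produce non-converging fits, reported as `div` rather than masked.
* The hidden-state propagation ignores observed-hidden correlations; with
  long intervals or strongly coupled species the partial-observation
  estimates degrade before the fully observed ones do.
* Joint noise estimation is attenuation-biased at coarse sampling (see
  above).
* The objective scores one-step transitions only; it neither yields
  confidence intervals nor a goodness-of-fit test — the residual check is
  the only built-in diagnostic, and it is one-sided in spirit.
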
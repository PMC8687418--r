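# mssinfer

Deterministic likelihood-based parameter estimation for discretely observed
stochastic chemical reaction networks, by **multiple shooting with
LNA-based Gaussian transition probabilities**.

## The problem

Reaction networks with small molecule counts — gene circuits, predator–prey
populations, birth–death processes — are continuous-time Markov jump
processes. Given counts ν₀, …, νₙ measured at times t₀ < … < tₙ, the
likelihood of a kinetic parameter vector θ factorises into one-step
transition probabilities p(νᵢ | νᵢ₋₁, Δᵢ, θ). Those transition
probabilities have no closed form in general, and estimating them by
stochastic simulation or by solving the chemical master equation is
expensive and scales badly.

`mssinfer` implements the *extended multiple shooting for stochastic
systems* estimator: each transition probability is approximated by a
Gaussian whose

- **mean** is the reaction-rate ODE solution over the single interval
  [tᵢ₋₁, tᵢ], restarted at the previous **datum** (the multiple-shooting
  step), and whose
- **covariance** is the linear noise approximation integrated over the same
  interval from Σ(0) = 0:  dΣ/dt = JΣ + ΣJᵀ + Ω⁻¹D, with drift Jacobian
  J = S ∂v/∂x and diffusion Dᵢⱼ = Σₖ Sᵢₖ Sⱼₖ vₖ evaluated along the
  interval mean.

The resulting negative log-likelihood

F(ν, θ) = − Σᵢ log 𝒩(νᵢ; x(Δᵢ; θ, νᵢ₋₁), Σ(Δᵢ; θ))

is completely deterministic (no simulation in the loop), costs one
integration of D + D(D+1)/2 equations per interval, and is minimised with a
quasi-Newton optimiser on log θ. Because the Gaussian approximation is only
required to hold *between* consecutive measurements, the estimator copes
with strongly stochastic regimes — extinctions, explosions, noise-driven
dynamics — where a global Gaussian approximation of the whole trajectory
fails. Partially observed species (propagated deterministically between
intervals, initial values optimised or known) and additive Gaussian
measurement noise (covariance inflation Σ + Σ_meas, σ optionally estimated)
are supported, as is the predecessor constant-variance objective for
comparison.

The package also provides exact Gillespie simulation for pseudo-data, the
closed-form immigration-death transition law (an independent oracle and an
exact reference estimator), a residual-based check of the approximation
(standardised one-step residuals must be i.i.d. N(0,1)), and a replicated
simulation-study harness reporting the replicate average (`av`), average
relative error (`ARE`), median relative error (`medRE`) and
non-convergence count (`div`).

## Worked example

Simulate an immigration–death process (influx θ₁ = 0.6, per-capita decay
θ₂ = 0.03) at its steady state, then recover the parameters from one
trajectory:

```r
library(mssinfer)

net <- immigration_death_network()
ts  <- ssa_simulate(net, x0 = 20, t_grid = seq(0, 1000, by = 10),
                    theta = c(0.6, 0.03), seed = 2)
fit <- mss_fit(ts, net, theta_init = c(1, 0.1))
fit
```

```
Multiple-shooting fit (extended LNA objective)
estimates:
 theta1  theta2 
0.70840 0.03248 
-log likelihood: 259.743  (converged)
```

The residual diagnostic checks the Gaussian approximation (n residuals for
n + 1 measurements; pass = compatible with N(0, 1)):

```r
normality_check(residuals(fit))
```

```
  species        mean      var    ks_stat   p_value pass
1       X 0.003461661 1.034512 0.05269251 0.9440742 TRUE
```

Both parameters are identifiable from a single stochastic trajectory —
here to within about 20% — even though a deterministic least-squares fit
of this design could only identify their ratio. A replicated study quantifies the
estimator's spread over many trajectories:

```r
sc <- mss_scenario("immigration_death", theta_true = c(0.6, 0.03),
                   x0 = "steady_state", n_points = 101, dt = 10,
                   n_replicates = 100, base_seed = 2000)
run_study(sc)
```

```
study scenario: immigration-death, 101 points at dt = 10, theta0 = (0.6, 0.03)
extended estimator, 100 replicates, base seed 2000
           theta1   theta2
true       0.6000  0.03000
av         0.6075  0.03059
ARE (%)   11.1600 11.34000
medRE (%)  8.4220  9.92000
div: 0 of 100 replicates
```

`av` near the truth shows the estimator is essentially unbiased in this
design; `ARE` ≈ 11% is the average relative spread of single-trajectory
estimates, driven by the intrinsic stochasticity of the data rather than
by the estimation method.

Partial observation and measurement noise use the same interface, e.g.
`mss_fit(ts, lotka_volterra_network(), theta_init, observed = "Y1",
hidden_init = 79)` for a predator–prey series in which only the prey is
measured.

A thin command-line front end over the same functions is installed at
`inst/cli/mss.R` (subcommands `simulate`, `objective`, `estimate`,
`check`, `study`).

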
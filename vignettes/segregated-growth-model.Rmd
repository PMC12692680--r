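---
title: "A timeline-segregated model of batch bacterial growth: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A timeline-segregated model of batch bacterial growth: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segrowth)
```

## The model

`segrowth` simulates batch growth of one or two bacterial strains — the
motivating system is the probiotic *Lactobacillus acidophilus* together
with *Escherichia coli* on SSCM (a glucose/mineral-salts synthetic medium)
or MRS broth — with the population of each strain *segregated in time*:
cell birth is a discrete event. When the cells of a strain have doubled
their mass, every cell divides in half. The mother cells continue their
own timelines while the newborn daughters found a new *generation cluster*
with its own birth time. Because aging is neglected, mothers and daughters
grow at the same specific rate and therefore divide again *synchronously*:
at the k-th division every existing cluster halves its concentration and
the removed halves together form generation k+1. A strain that has divided
k times therefore consists of exactly k + 1 clusters.

Between divisions the dynamics are smooth mass balances (concentrations in
g/L, time in h). Each cluster of strain *i* grows by Monod kinetics on the
single shared substrate S and dies by a first-order process,

$$\frac{dX_i^k}{dt} = \mu_i(S, P)\, X_i^k - k_{d,i}\, X_i^k, \qquad
  \mu_i(S, P) = \frac{\mu_{max,i}\, S}{K_{S,i} + S}$$

Dead cells of both strains join a single shared pool $X_d$, which lyses
back into substrate after a lag $\theta$ at rate $k_s X_d(t - \theta)$ —
dead biomass is fully recycled as a carbon/nitrogen source:

$$\frac{dX_d}{dt} = \sum_i \sum_k k_{d,i} X_i^k - k_s X_d(t-\theta), \qquad
  \frac{dS}{dt} = -\sum_i \sum_k \frac{\mu_i}{Y_{XS,i}} X_i^k
                  + k_s X_d(t-\theta)$$

In co-culture a lactic-acid state P couples the strains: the producer
(*L. acidophilus*) accumulates P in proportion to its growth,
$dP/dt = \sum_k (\mu_m / Y_{XP}) X_m^k$, and the inhibited strain
(*E. coli*) sees it as an extra term in its Monod denominator,
$\mu_n = \mu_{max,n} S / (K_{S,n} + S + P/K_P)$. The roles are assigned
functionally — producer and inhibited are per-strain flags — rather than
by species name, and the whole lactic-acid coupling is active by default
only in two-strain scenarios (it can be toggled per scenario). A strain
cannot be both producer and inhibited: the single inhibition mechanism in
the model is the producer's action on the other strain, and a
self-inhibited producer would be a different model.

### The division trigger

The qualitative rule — cells divide when they have grown to a certain
mass — leaves the quantitative trigger open. `segrowth` gives each strain
a *division clock*: the cumulative gross specific growth
$\int \mu_i\,dt$ since the strain's last division. When the clock reaches
$\ln 2$ the average cell mass has doubled, every cluster halves, and the
clock resets. Three consequences match the qualitative behaviour the
model is meant to reproduce:

* all clusters of a strain share one $\mu_i$, so they divide together
  (synchrony);
* strains carry independent clocks, so faster strains accumulate more
  clusters;
* when the substrate is exhausted $\mu \approx 0$, the clocks stall, and
  cells neither grow nor divide (stationary phase needs no extra rule).

The clock integrates the *gross* growth rate, not $\mu - k_d$: death
removes whole cells from a cluster and does not make the surviving cells
lighter. A strain with zero viable biomass has its clock frozen — there
are no cells whose mass could double — so an inert (zero-inoculum) strain
generates no division events.

## Numerical treatment

The system is hybrid (smooth flows plus discrete events) and delayed (the
lysis term). `simulate_culture()` integrates it with `deSolve::lsodar`,
the adaptive stiff/non-stiff switching solver with built-in root finding:

* **Division events** are located by a root function on the clocks
  ($\text{clock}_i - \ln 2$), not detected at step ends, so division times
  are accurate to the solver tolerance. At the root the state is rewritten
  (halve clusters, append the new one, reset the clock) and integration
  restarts.
* **The delay** is handled by the method of steps: between events the
  integration proceeds in segments no longer than $\theta$, evaluating
  $X_d(t - \theta)$ against a dense linearly-interpolated history recorded
  from completed segments (the history is identically zero before the
  culture starts). The internal step is capped at $\theta/4$ so each
  segment contributes at least four history nodes. Delays at or below
  $10^{-6}$ h are treated as zero (the plain-ODE limit); a regression test
  checks that $\theta = 10^{-9}$ and $\theta = 0$ give identical
  trajectories.
* **Non-negativity.** The rate laws evaluate $\max(S, 0)$, so a tiny
  numerical undershoot of the substrate cannot feed back; an additional
  root at $S \approx 0$ logs a `substrate_exhausted` event. Because the
  delayed drain $k_s X_d(t-\theta)$ may exceed what the dead pool
  currently holds, the drain is capped at $k_s X_d(t)$; the same (capped)
  flux enters S, so the cap never breaks mass conservation. Lysis can lift
  S above zero again after exhaustion, which produces the characteristic
  small rebounds on the substrate depletion curve.
* **Event ordering** at coincident times is deterministic: inoculations
  are segment boundaries and are applied before division roots located in
  the following segment; simultaneous division roots of the two strains
  are applied in strain order.
* Default solver tolerances are `rtol = 1e-7`, `atol = 1e-9`. Against an
  independent fixed-step Euler reference at $h = 10^{-3}$ h the adaptive
  integrator agrees within 0.5% (scaled sup-norm per state component) on
  all four mono-culture presets over 48 h; the test suite enforces this.

The simulator was deliberately *not* given a lag-phase mechanism. The lag
periods seen in growth experiments (5–20 h depending on strain and
medium) reflect enzymatic adaptation that the mass balances above do not
describe; with the preset constants the simulated cultures start growing
immediately. Reproducing measured lag durations is out of scope, and
parameter-recovery results below must be read as statements about the
model, not about any laboratory culture.

## Calibration

`culture_objective()` implements the regression objective: the root mean
square residual, over the observation times, between modelled and
observed *viable* biomass of every observed strain, in g/L,

$$F_{OB} = \sqrt{\frac{1}{N} \sum_{t_i} \sum_{\text{strains}}
  \left(X^{tot}_{model}(t_i) - X_{obs}(t_i)\right)^2}$$

Substrate measurements do not enter the objective; they are carried along
for plotting and for the identifiability diagnostic. The residual is not
normalized by the observation mean, so $F_{OB}$ keeps units of g/L; an
optional per-point weight vector generalizes the mean. In co-culture the
residuals of both strains pool into one objective (flow cytometry
resolves the two strains separately, so both series exist); per-strain
RMSEs can be computed by passing a single-column observation series.

`fit_culture()` minimizes $F_{OB}$ over finite positive box bounds with a
real-coded genetic algorithm: tournament selection (size 3), blend
crossover (BLX-$\alpha$, $\alpha = 0.5$, probability 0.9), Gaussian
mutation (per-gene probability 0.15, s.d. 10% of the range), elitism 1,
population 40, 60 generations. Because kinetic constants span orders of
magnitude, the search runs in $\log_{10}$ space and the initial
population is log-uniform over the bounds. Differential evolution
(rand/1/bin, F = 0.7, CR = 0.9) is a drop-in alternative
(`fit_settings(method = "de")`). A deterministic two-stage polish refines
the best individual, still in log space and within the bounds: a bounded
quasi-Newton step (L-BFGS-B, at most 60 iterations) followed by a
Nelder-Mead simplex descent. The second stage matters: parameters that
compensate for each other (for instance the death and lysis constants
against the Monod pair after substrate exhaustion) form long, shallow,
curved valleys along which finite-difference gradients are smaller than
the event-induced kinks in the objective, so quasi-Newton iterations
stall; the simplex tracks such valleys reliably and, on noiseless
synthetic data, takes the solution from the GA's basin to the optimum
itself (objective values around $10^{-9}$ g/L).

Compensated optima are still possible: the post-exhaustion data can be
almost equally well described with a much larger lysis constant and
slightly shifted Monod constants, and both the GA and DE reliably find
that local optimum first, leaving $k_s$ pinned against its upper bound.
A parameter sitting on a search bound is the tell-tale; `fit_culture()`
warns when it sees one. The opt-in remedy,
`fit_settings(profile_restarts = TRUE)`, runs a one-parameter profile
sweep after the polish: the simplex is re-launched from three interior
values of each free parameter in turn (skipping parameters the
objective is verifiably flat in), and the two best endpoints are
descended to convergence. This roughly doubles the cost of a fit, which
is why it is not the default. On the noiseless recovery studies this
step is what separates four-of-five recovery from
all-five-at-machine-precision. A failed simulation
during the search is penalized with a large finite objective
($10^6$ g/L) rather than aborting the fit. Every random draw is governed
by two seeds — one for the initial population, one for the genetic
operators — so a fit is exactly reproducible.

### The ten-run uncertainty protocol

Evolutionary optimizers do not come with standard errors.
`uncertainty_protocol()` therefore repeats the fit exactly ten times:
five runs keep the base initial population and vary the operator seed,
and five runs keep the base operator seed and vary the initial
population. The per-parameter mean and *sample* standard deviation
(N − 1 denominator; ten values) summarize the spread. On a convex
objective all ten runs coincide and the standard deviations collapse to
numerical zero, which the acceptance suite checks.

### Identifiability

When the substrate stays far below $K_S$ throughout an experiment, only
the ratio $\mu_{max}/K_S$ is constrained by the data — the extreme preset
(`lacidophilus_sscm`, $K_S = 1.12 \times 10^4$ g/L with
$\mu_{max} = 147$ 1/h) is best read this way. `fit_culture()` warns
whenever the largest substrate level the data could have seen is below
10% of a fitted $K_S$. For the recovery studies the initial substrate is
deliberately raised (S0 = 200 g/L for the *E. coli* presets, 2000 g/L
for `lacidophilus_mrs`) so the trajectory sweeps S from well above to
well below $K_S$ and all five parameters are individually identifiable.
Death and lysis constants are informed by the post-exhaustion phase,
where viable biomass decays and recycled substrate sustains a slow
regrowth, so the 48 h horizon (24 h for the fast-growing
`lacidophilus_mrs` case) matters.

## Synthetic observations

`generate_observations()` emulates the study design the estimator is
meant for: hourly sampling of per-strain viable biomass
(flow-cytometry-like) and of reducing sugar (DNS-like), with independent
multiplicative lognormal noise of fixed coefficient of variation
(default 5%). The lognormal factor is mean-one
($\exp(\sigma Z - \sigma^2/2)$, $\sigma^2 = \log(1+cv^2)$), so the noise
is unbiased — a Monte-Carlo test checks this — positive by construction,
and scales with the signal, which is how counting and colorimetric
measurements behave to first order. A detection floor (default
$10^{-6}$ g/L) clamps values from below. What the generator does *not*
emulate: gating errors that cross-assign the two strains, correlated
drift between consecutive samples, the lag phase discussed above, or any
pH/oxygen feedback. Passing recovery tests on these synthetic data
therefore demonstrates the estimator's correctness, not field accuracy
on real cytometry series.

Initial conditions for the presets are package choices, not reported
values: inoculum 0.01 g/L per strain and S0 = 1 g/L for SSCM (from its
recipe: 5 mL of 20% glucose per litre) and 20 g/L for MRS (its standard
sugar load), all overridable. The lysis lag defaults to
$\theta = 2$ h. The co-culture templates additionally need $K_P$ and
$Y_{XP}$, which were never reported; the neutral placeholders
($K_P = 1$, $Y_{XP} = 1$) are flagged in the scenario's
`unreported_defaults` attribute and are meant to be replaced by
user-supplied values. The second sub-row of the published co-culture
parameter block cannot be unambiguously mapped to strains and
parameters, so the templates reuse the mono-culture constants instead of
guessing.

## Worked example

A mono-culture recovery study at desk scale: simulate *E. coli* on SSCM
with S0 raised to 200 g/L, then re-fit $\mu_{max}$ from the noiseless
series.

```{r example, eval = FALSE}
sc <- scenario_presets("ecoli_sscm", S0 = 200, horizon = 48)
obs <- generate_observations(sc, noise_model("none"))
spec <- fit_spec(sc, list("ecoli:mu_max" = c(0.1, 10)),
                 fit_settings(pop_size = 12, generations = 8), seed = 42)
fit_culture(obs, spec)
```

The full five-parameter recoveries (the `scripts/acceptance.R`
benchmark) use population 40 for 60 generations plus the polish —
five to eight thousand objective evaluations, i.e. as many simulated
batch cultures, per fit, a few minutes each on one core. The problem sizes
(hourly sampling, 24–48 h horizons, three presets) were chosen so that a
complete benchmark remains an interactive-scale computation.

## Known limitations

* Death is uniform: $k_d$ applies identically in lag, exponential and
  stationary phases, because nothing in the model distinguishes them.
* The dead pool is shared and unstructured; strain-resolved dead biomass
  would need per-strain lysis constants and is not implemented.
* No maintenance metabolism: when $\mu = 0$, cells consume nothing.
* The division clock is strain-global. Sub-populations desynchronized by
  transient gradients cannot be represented; generation clusters are the
  only population structure.
* $F_{OB}$ values from different data sets are comparable only if the
  observation units and sampling grids match, since the objective is an
  unnormalized RMSE.
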
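---
title: "Methods: size-structured consumer-resource dynamics and the evolution of metabolic scaling exponents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: size-structured consumer-resource dynamics and the evolution of metabolic scaling exponents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`debevo` implements a size-structured consumer-resource model built on a
net-production dynamic energy budget (DEB). A consumer individual is
described by its body mass $s$ (g); the shared environment is a single
resource density $R$ (mg/L) renewed by semi-chemostat dynamics
$G(R) = \delta(R_{max} - R)$. The individual-level rates are

* ingestion $I(R,s) = M\,(s/s_r)^Q\,R/(R+H)$ — a Holling type-II
  functional response with an allometric maximum;
* net biomass production $\Omega(R,s) = \sigma I(R,s) - T\,(s/s_r)^P$ —
  assimilation minus maintenance, maintenance paid first;
* growth $g(R,s) = \kappa(s)\,\Omega^+(R,s)$ and fecundity
  $b(R,s) = (1-\kappa(s))\,\Omega^+(R,s)/s_b$, where
  $\Omega^+ = \max(\Omega, 0)$ and $\kappa(s)$ is a cubic smoothstep that
  falls from 1 at the maturation mass $s_j$ to 0 at the maximum mass $s_m$
  (juveniles allocate everything to growth);
* mortality $\mu(R,s) = \mu_c + \mu_{j|a} - \Omega^-(R,s)/s$ — background
  plus stage-specific mortality plus a mass-specific starvation term active
  only when production is negative ($\Omega^- = \min(\Omega, 0)$);
  individuals do not shrink.

The exponents $Q$ and $P$ set how maximum ingestion and maintenance scale
with body mass, and thereby how *competitive ability* changes over
ontogeny. The natural summary is the maintenance resource density (MRD),
the resource level at which an individual of mass $s$ just covers
maintenance:

$$\mathrm{MRD}(s) = \frac{H\,\theta(s)}{\sigma M - \theta(s)}, \qquad
  \theta(s) = T\,(s/s_r)^{P-Q}.$$

For $P > Q$ the MRD rises with size (small individuals are superior
competitors); for $Q > P$ it falls; for $Q = P$ it is independent of size
and competition is symmetric. `maintenance_resource_density()` returns
`Inf` when $\theta \ge \sigma M$ (maintenance can never be covered), so
parameter sweeps over extreme exponents degrade gracefully instead of
aborting.

Default parameter values are the standard parameterization shipped in
`inst/extdata/defaults.yaml` (resource: $R_{max} = 30$ mg/L,
$\delta = 0.01$/d, $H = 3$ mg/L; energetics: $M = 0.1$ g/d, $T = 0.01$
g/d, $\sigma = 0.5$, $Q = P = 1$; sizes: $s_b = 0.1$, $s_j = s_r = 1$,
$s_m = 10$ g; mortality: $\mu_c = 0.0015$/d, $\mu_j = \mu_a = 0$). The
reference mass $s_r$ sits at the maturation mass so that changing an
exponent trades juvenile against adult performance; `deb_params()` warns
when $s_r$ leaves $[s_b, s_m]$ because the trade-off then degenerates and
selection on the exponents becomes directional.

### Units and the conversion constant `chi`

Resource density carries mg/L while consumer mass carries g; the constant
`chi` (default 1, a unit-volume system) converts total consumer ingestion
(g/day) into resource depletion (mg L$^{-1}$ d$^{-1}$). Because `chi`
enters only the linear resource balance, the equilibrium resource density,
$R_0$, and every evolutionary output are provably independent of it — it
rescales only the population birth rate and absolute biomasses. The test
suite asserts this invariance rather than assuming it.

## Life history and the ecological equilibrium

At fixed $R$, `life_history()` integrates
$$\frac{ds}{da} = g(R,s),\quad \frac{dF}{da} = -\mu(R,s)F,\quad
  \frac{dB}{da} = b(R,s)F,\quad \frac{d\Theta}{da} = I(R,s)F$$
with `deSolve` (lsoda with root functions). Maturation is an exact event
(root of $s - s_j$), so stage-specific mortality switches at the precise
age rather than at a grid crossing. Integration runs to a survivorship
cutoff of $10^{-9}$ (not a fixed horizon): with $\mu_c = 0.0015$/d,
meaningful reproduction extends to $\sim 10^4$ days, and the neglected
tail then contributes less than $10^{-6}$ of lifetime reproduction
(asserted by a cutoff-halving test). A hard age cap of $10^5$ days is a
backstop. When the resource cannot cover maintenance even at the size at
birth the trajectory is degenerate (no growth, constant hazard) and is
written in closed form instead of integrated.

The terminal value of $B$ is $R_0$, the expected lifetime reproductive
success. $R_0(R)$ is continuous and strictly increasing wherever positive,
so the ecological equilibrium condition $R_0(\tilde R) = 1$ has a unique
root on $(0, R_{max})$, which `solve_equilibrium()` brackets and solves
with Brent's method (`uniroot`, tolerance $10^{-10}$). The population
birth rate follows from the resource balance
$\tilde b = \delta(R_{max} - \tilde R)/(\chi\,\Theta_\infty(\tilde R))$,
and stage biomasses and fluxes are quadratures over the already-solved
trajectory (three extra bookkeeping integrals are carried by the same ODE
solve, so nothing is re-integrated). If $R_0(R_{max}) \le 1$ the consumer
is not viable and an explicit extinct-equilibrium marker is returned.

Starvation never occurs at equilibrium (the equilibrium resource density
exceeds the MRD of every realized size), which is why the starvation
mortality term matters only for the non-equilibrium simulator below.

## Cohort simulation (Escalator Boxcar Train)

`ebt_simulate()` integrates the full size distribution as a set of
cohorts, each carrying a number density and a mean mass, coupled to the
resource. The inner loop is C++ (the established codes for physiologically
structured populations are C as well): classical RK4 steps of 0.5 d
between boundary-cohort closures every 2.5 d, at which the newborns pooled
from all cohorts' reproduction are inserted as one cohort at the size at
birth (a first-order EBT variant). The model's rates are smooth and slow
(at most $\sim 0.1$/d), so RK4 at this step is far inside its accuracy
range; a refinement test (halving both steps changes long-run averages by
well under 0.5%) backs this up.

Two details keep the cohort count bounded over the $2$–$6 \times 10^4$
day horizons used for cycle detection:

* cohorts whose masses have converged (all near the asymptotic size) are
  merged, number-weighted, once older than 150 d and closer in mass than
  0.2% — the standard practical device for cohort pile-up at an attractor
  of the growth trajectory;
* cohorts are removed when their numbers fall below $10^{-12}$ of their
  *lineage's* initial total. Making the cutoff lineage-relative matters:
  in two-lineage (mutant-invasion) runs, a cutoff relative to the whole
  population silently erodes the rare lineage and biases invasion
  outcomes — this failure mode was observed and is guarded by the
  neutral-mutant drift test.

A 1-day closure interval was considered and rejected: with background
mortality 0.0015/d a cohort persists for $\sim 1.8\times10^4$ days, so
daily closure yields tens of thousands of concurrent cohorts for no
measurable accuracy gain.

`detect_cycles()` classifies a run as cyclic when the relative
peak-to-trough resource amplitude after a transient exceeds 1%, and
estimates the period from the spacing of resource maxima. The adult-driven
cycles this model produces for $Q > P$ are slow (period $\approx 4600$ d
at $Q = 1.2$, $P = 1$), so cycle tests use windows of $\ge 10^4$ days
after a $2\times10^4$ day transient.

`invasion_experiment()` runs a resident to its attractor, introduces a
rare mutant lineage ($10^{-6}$ of resident biomass, as newborns), and
follows both lineages sharing one resource. For cyclic residents the
mutant is introduced at a resource maximum by default (the introduction
phase is an option), and the long-run trend of the mutant biomass share is
read at matching cycle phases (resource maxima) — raw share values
oscillate strongly within a cycle and would otherwise confound the trend.
For stable residents, averages over late windows are compared, both past
the initial age-structure transient of the newly seeded lineage.

## Adaptive dynamics

The environment feeds back on an individual only through $\tilde R$, so a
mutant's invasion fitness is simply its $R_0$ at the resident's
equilibrium resource density (`mutant_R0()`). Selection gradients are
central finite differences in the mutant trait (step $10^{-4}$ in
exponent units; step-halving changes the gradient by $< 10^{-5}$
relative, so truncation and ODE noise are both under control).
Variational ODEs would be more elegant; finite differences are simpler,
verifiably accurate here, and documented as replaceable.

`find_css()` locates a singular strategy of one exponent by bracketed
root finding on the gradient over the resident trait, re-solving the
resident equilibrium at every evaluation (warm-started brackets).
Classification follows the standard second-order conditions: mutant
curvature $< 0$ for evolutionary stability, gradient slope across
residents $< 0$ for convergence stability; because the environment is
one-dimensional, singular points here are both (continuously stable
strategies, CSS). Curvatures are measured with a wider step (0.02) than
the gradient, since second differences amplify solver noise; a curvature
smaller than $10^{-6}$ in magnitude is reported as near-neutral rather
than classified. The solver also verifies the model's geometric
signature: $\tilde R$ is locally minimized at a CSS (pessimization: the
evolutionary winner is the phenotype that persists at the lowest
resource level).

`find_joint_css()` solves both gradients simultaneously with a damped
quasi-Newton iteration (forward-difference Jacobian, step $10^{-3}$;
steps capped at 0.1 in trait space; halving on non-decrease of the
gradient norm). A 2-D root solve is used instead of alternating 1-D
relaxations because the two isoclines lie nearly on top of each other,
which makes alternation ill-conditioned. Convergence is declared at
gradient norm $2\times10^{-4}$, consistent with the finite-difference
noise floor; in practice the iteration lands with $|\bar Q - \bar P|$
below $10^{-6}$. `css_sweep()` continues the joint solution along a
parameter grid, warm-starting from the neighbouring point, and attaches
the stage-structured equilibrium outputs at each singular point.
`reproduction_scaling_check()` regresses the log reproductive biomass
flux on log mass over the realized adult range (trimmed 5% at each end,
where the flux vanishes by construction) — at the default joint CSS the
fitted exponent exceeds one: realized reproduction is hyperallometric
even though the MRD is size-independent there.

## The regression module and its synthetic data

`rma_fit()` implements reduced major axis regression — slope
$\mathrm{sign}(r)\,s_y/s_x$ — with the closed-form slope standard error
$|b|\sqrt{(1-r^2)/(n-2)}$ and Student-t intervals by default (a case
bootstrap is the option; the choice between them is not material on data
of this shape, and both are exposed). `simulate_exponent_records()`
generates the comparative dataset this is meant for: metabolic scaling
exponents of $n = 41$ species against the log ratio of maturation length
to egg diameter, uniform predictor on $[3, 7]$ (natural log; ratios of
$\sim$20 to $\sim$1100, spanning small-egg marine spawners to
large-offspring bearers), intercept 1.3, slope $-0.1$ and Gaussian noise
with SD 0.08, chosen so the generated exponents fall in the empirically
typical 0.6–1.2 band with a shallow, significantly negative trend. The
generator emulates none of the structure of real comparative data beyond
this — no phylogenetic covariance, no temperature correction, no
measurement-error heterogeneity — so the coverage and recovery tests
validate the estimator, not any claim about real fish.

## Numerical settings and test problem sizes

Defaults: ODE tolerances $10^{-8}$ (relative) and $10^{-10}$ (absolute);
root tolerance $10^{-10}$; survivorship cutoff $10^{-9}$;
finite-difference step $10^{-4}$. The test suite solves joint singular
points at the default and small-$s_b$ parameterizations, a 9-point
isocline over $P \in [1.0, 1.4]$, mortality and size-range sweeps of 2–3
points each, and cohort simulations of up to $3.2\times10^4$ days —
sizes chosen to exercise every solver path at full accuracy while keeping
a complete run of the suite in the minutes range.

## Known limitations

* Stability of equilibria is decided by simulation (perturbation decay
  versus sustained oscillation), not by spectral analysis of the
  linearized structured model; cycle boundaries are therefore reproduced
  qualitatively, and "the largest individual in the population" under
  cycles is reported as the maximum over the live cohort set, which has
  no unique definition off equilibrium.
* The individual model has no reserves, no shrinking under starvation,
  and no stochastic individual variation; the starvation term only
  raises mortality.
* The joint singular point's second-order geometry has a near-neutral
  direction along $Q = P$; curvature diagnostics are reported but a 2-D
  classification is deliberately not asserted when the curvature is
  below the noise threshold.
* Invasion outcomes in cyclic attractors are read from finite runs
  ($\sim 4$–$12$ cycles); selection coefficients much smaller than the
  run length resolves are reported as neutral.
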
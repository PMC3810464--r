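---
title: "Minimum-cost reintroduction in a two-sex reaction-diffusion model"
author: "reintro package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum-cost reintroduction in a two-sex reaction-diffusion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reintro)
```

## The model

`reintro` treats the reintroduction of a dioecious species into a large,
one-dimensional habitat as a constrained optimization: find the initial
spatial distribution of released females and males that restores the
population throughout the habitat at the smallest cost, where cost is the
number of individuals released (constant per-capitum cost, so cost is the
integral of the initial densities over space, summed over the sexes).

The population dynamics is a two-sex reaction–diffusion system for the
local female and male occupancy fractions $f(x,t)$ and $m(x,t)$:

$$
\partial_t f = D_f\, \partial_x^2 f + \sigma\, r\, f m\,(1 - f - m) - \mu_f f,
\qquad
\partial_t m = D_m\, \partial_x^2 m + \sigma (1-r)\, f m\,(1 - f - m) - \mu_m m .
$$

Births require encounters between the sexes (mass action, $f m$), succeed
in proportion to the unoccupied fraction of the environment ($1-f-m$,
self-regulation), and are split between the sexes by the birth sex ratio
$r$ (fraction born female). Each sex disperses by homogeneous diffusion
($D_f$, $D_m$) and dies at a density-independent rate ($\mu_f$, $\mu_m$).
The birth-rate scale $\sigma$ (default 1) sets the time unit; all
thresholds below scale with it.

Because reproduction needs both sexes *and* density, the local dynamics
has a strong Allee effect: below a positive density threshold the
population declines even without dispersal. Writing
$A = \mu_f/r + \mu_m/(1-r)$, positive equilibria exist iff $A < \sigma/4$;
the vacant fraction $s = 1-f-m$ then solves $s(1-s) = A/\sigma$, the
smaller root giving the stable persistence state and the larger root the
unstable Allee point ([`equilibria()`]). The equilibrium total density
depends on $r$ only through $A(r)$, so the density-maximizing sex ratio
has the closed form $r^* = \sqrt{\mu_f}/(\sqrt{\mu_f}+\sqrt{\mu_m})$
([`optimal_sex_ratio()`]).

Setting $r = 1/2$, $\mu_f = \mu_m = \mu$, $D_f = D_m = D$ and identical
initial distributions makes the two equations identical, $f = m = u$,
with the scalar Nagumo-type equation

$$
\partial_t u = D\,\partial_x^2 u + \tfrac{\sigma}{2} u^2 (1 - 2u) - \mu u
           = D\,\partial_x^2 u - \sigma u (u - u_-)(u - u_+),
\qquad u_\pm = \tfrac14 \pm \sqrt{\tfrac1{16} - \tfrac{\mu}{\sigma}} .
$$

The reduction is implemented so that a symmetric two-sex integration and
the scalar integration produce bit-identical trajectories (same
floating-point operation order in the kernels), which the test suite
asserts.

## Release designs and how each is optimized

**Aperiodic stationary profile (critical nucleus).** Stationary profiles
of the scalar equation conserve $E = (D/2)(u')^2 + G(u)$ with
$G(u) = \sigma u^3/6 - \sigma u^4/4 - \mu u^2/2$ ([`first_integral()`],
[`allee_potential()`]). In the spreading regime $G(u_+)>0$ (below the
Maxwell point $\mu = \sigma/18$, computed numerically, never assumed) the
$E=0$ separatrix is a homoclinic loop through the extinction saddle: a
localized, symmetric, unstable profile whose peak $u_{\max}$ solves
$G(u_{\max})=0$ on $(u_-,u_+)$. [`aperiodic_profile()`] integrates the
profile outward from the peak (quartic series at the peak, where the
phase-plane square root degenerates, then `deSolve::lsodar` at
`rtol = atol = 1e-12` with a root stop at the truncation threshold),
truncates it at a small density (default `1e-3`; the cost is reported
with and without an analytic tail estimate $4\,\mathrm{thr}\sqrt{D/\mu}$),
and returns it on a uniform grid so it can be injected directly into the
PDE. Scaled up by 1% it restores; scaled down by 1% it collapses — the
profile *is* the basin boundary.

**Rectangular clusters.** For homogeneous clusters of densities
$(n_f, n_m)$ and lengths $(L_f, L_m)$ centered in the habitat, the cost is
$n_f L_f + n_m L_m$. [`critical_length()`] finds the smallest common
length that restores, by doubling then bisection, classifying every
candidate with a full PDE integration; [`critical_density()`] does the
converse at fixed length. Release densities default to the
persistence-equilibrium densities: the density scan
([`cost_vs_density_scan()`]) shows the true cost minimum sits slightly
below the equilibrium density but the advantage is small (under 2% at the
canonical parameters), so the equilibrium densities are a good
parameter-driven default.

**Sex-specific cluster lengths.** [`optimize_unequal()`] minimizes
$C(L_f) = n_f L_f + n_m L^{crit}_m(L_f)$, where the critical male length
at fixed female length comes from a nested binary search
([`critical_male_length()`]). The female length moves in unit steps of
one grid cell, continuing through flat stretches (discretization
plateaus) and stopping after `patience` consecutive cost increases; the
cost is assumed convex in the lengths and a rise-then-fall trace beyond
the lattice cost quantum is flagged. At $r = r^*$ the equal-cluster
design is already optimal (ratio $R = 1$); as $r$ departs from $r^*$,
$R$ falls below 1 and the savings grow.

**Free shapes by simulated annealing.** [`anneal()`] performs Metropolis
Monte-Carlo over discretized per-cell release densities for both sexes.
Moves perturb a uniformly chosen occupied cell of a uniformly chosen sex
by $\mathrm{unif}(-a,+a)$ (clipped to the occupancy simplex $f+m\le 1$),
or grow/shrink the support by one edge cell (probabilities 0.8/0.1/0.1).
A cost-increasing move is accepted with probability $e^{-\Delta C/T}$;
every accepted move is then screened by a full PDE integration and
rejected outright if the shape fails to restore, so the chain never
leaves the feasible region. The schedule (all configurable) sets $T_0$ to
the standard deviation of cost changes over 100 random feasible proposals,
cools geometrically by 0.95 per stage, and stops when the acceptance rate
collapses below 1% or `max_stages` is reached. The claim is
best-visited-feasible under a finite schedule, not a global optimum; the
reported state is re-verified by a fresh integration.

## Numerical scheme and its guard rails

The integrator is explicit Euler with the standard 3-point Laplacian,
written in C++ for the inner loop. Defaults and safeguards:

* **Time step.** $dt = \min\left(0.2\,\frac{dx^2}{2\max(D_f,D_m)},\;
  \frac{0.1}{\sigma + \max(\mu_f,\mu_m)}\right)$: the diffusion stability
  bound with a 5× safety margin, capped against reaction stiffness.
  Non-finite values abort with a diagnostic.
* **Boundaries.** No-flux by default (the habitat is auto-sized to six
  times the current search bound so boundaries stay inert); absorbing
  available.
* **Equilibrium detection.** Integration stops when the maximum absolute
  time-derivative over the grid falls below `tol_converge` (default
  `1e-8` per unit time, far below all dynamical scales used). The final
  mean total density within 10% (relative) of the persistence total is
  classified `PERSISTENCE`; below `1e-4`, `EXTINCTION`; hitting
  `max_time`, `NOT_CONVERGED`. The bistability makes any band between the
  equilibria equivalent; both thresholds are configurable.
* **Certified early exits.** A state everywhere strictly below the Allee
  equilibrium (componentwise) is already inside the extinction basin, and
  one everywhere strictly above it is inside the restoration basin — both
  by comparison with the homogeneous dynamics, which is order-preserving
  in the relevant region. The integrator exits as soon as either
  certificate holds, which shortens the many near-threshold runs a binary
  search performs by one to two orders of magnitude without changing any
  classification (spot-checked against full convergence runs in the
  suite). `early_exit = FALSE` disables it.
* **Occupancy simplex.** $f+m\le 1$ is validated on initial conditions
  only; the dynamics is attracted into the simplex and clipping mid-run
  would alter the scheme. Negative round-off values are clipped to zero.
* **Cluster lattice.** Each grid node is a cell of width $dx$; a cluster
  of length $L$ occupies exactly `round(L/dx)` cells (half-open interval
  membership), so binary searches run on the integer cell lattice, the
  discrete release mass matches $nL$ exactly for lattice lengths, and the
  searched outcome is monotone cell by cell. All length thresholds are
  therefore quantized to one cell; comparisons between designs are made
  on a common grid, since one-cell threshold classifications are only
  comparable within a single lattice.

## What the defaults emulate, and what they do not

The canonical parameter set used throughout the documentation and tests
is $\mu_f = \mu_m = 0.05$, $D = 1$, $r = 1/2$, $\sigma = 1$: bistable
($\mu < \sigma/16$), in the spreading regime ($\mu < \sigma/18$) but
close to the Maxwell point, where fronts are slow, critical clusters are
wide (critical length ≈ 11.6, about 47 cells at $dx = 0.25$), and the
cost landscape is well resolved. Heavier scans that need many PDE runs
use $\mu = 0.03$ or $\mu = 0.04$ (deeper in the spreading regime: faster
fronts, smaller clusters) with $dx$ chosen so the cluster spans at least
~25 cells wherever a claim about cost differences at the percent level is
tested. The sex-ratio scan for sex-specific clusters uses
$\mu = 0.04$ and scan points $r \in \{0.50, 0.415, 0.37, 0.335, 0.305\}$:
the spacing grows with the bias so that successive cost-ratio differences
exceed the one-cell cost quantum the lattice can resolve.

These are dimensionless study conditions (densities are occupancy
fractions; lengths are in units of $\sqrt{D/\mu}$-scale dispersal
distances), not a calibration to any species. The model ignores
demographic stochasticity, discreteness of individuals, non-diffusive
dispersal kernels, two-dimensional habitat geometry and front curvature,
and interspecific interactions; passing tests say the deterministic
one-dimensional model behaves as described, not that a real release of
that size would succeed.

## Worked example

```{r example, eval = FALSE}
p <- model_params(r = 0.5, mu_f = 0.05, mu_m = 0.05)
equilibria(p)

# cheapest rectangular release at the equilibrium densities
cl <- critical_length(p, dx = 0.25)
cl
cost_rectangular(cl$n_f, cl$n_m, cl$bracket[2])

# the critical nucleus costs noticeably more
prof <- aperiodic_profile(as_single_sex(p), threshold = 1e-3, dx = 0.05)
prof$cost

# full comparison, including simulated annealing
compare_methods(p, dx = 0.35,
                anneal_cfg = anneal_config(max_stages = 10,
                                           moves_per_stage = 100, seed = 7))
```

## Design choices where the design was genuinely open

* **Birth-term normalization.** $\sigma$ is kept as an explicit
  parameter (default 1) multiplying the mass-action birth term; the
  factor $1/2$ in the scalar reduction is then forced by the $f=m=u$
  substitution. Every closed-form consequence (the $\mu < \sigma/16$
  threshold, $u_\pm$, $r^*$) is validated against independent numerical
  oracles in the suite rather than trusted.
* **Stability labels** come from numerically differenced Jacobian
  eigenvalues (central differences, step $10^{-7}$), robust to any
  algebraic slip in hand-derived formulas.
* **Sub-threshold searches** signal a typed condition
  (`reintro_divergent`) rather than returning a sentinel, so scans can
  drop inadmissible points explicitly.
* **Annealing schedule.** The Boltzmann acceptance and geometric cooling
  are standard; the specific schedule constants ($T_0$ from proposal
  statistics, cooling 0.95, stop below 1% acceptance) are defaults, and
  all results reported from annealing depend only on cost ordering, not
  on the schedule.
* **Configuration files** are JSON (`load_config()`); profiles and
  tables are CSV with documented columns, reports JSON. No domain
  standard exists for these objects.
* **Period quadrature.** Near the center the integrand of the
  closed-orbit period suffers catastrophic cancellation; it is evaluated
  through the factored form $G(u)-G(u_-) = (u-u_-)^2 q(u)$ (synthetic
  division). Near the separatrix the slow passage at the extinction
  saddle is handled by an $u = u_1\cosh s$ substitution with stable
  `expm1`/`log1p` power differences, so periods remain accurate for
  orbits within $10^{-140}$ of the separatrix — close enough to exhibit
  the logarithmic divergence over two orders of magnitude.

## Known limitations

* Critical lengths are resolved to one grid cell; claims finer than the
  lattice cost quantum (about $1/(2k)$ of the cost for a $k$-cell
  cluster) cannot be tested at a given $dx$ and need a finer grid.
* The two-sex system is not order-preserving everywhere, so the
  monotonicity that justifies binary search is a theorem only for the
  scalar reduction; for the two-sex system it is verified empirically by
  re-simulating both bracket endpoints.
* Simulated annealing with the PDE-feasibility constraint is expensive;
  the default problem sizes (grids of a few hundred cells, tens of
  stages) explore the neighborhood of the rectangular optimum rather
  than the full shape space. Consistently with that, its best shapes are
  arch-like trims of the rectangle with essentially identical cost.
* `NOT_CONVERGED` outcomes are treated conservatively (failure/infeasible)
  with a warning; raise `max_time` if they appear in a scan.
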
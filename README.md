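# reintro

Minimum-cost species reintroduction in a two-sex reaction–diffusion model
with a strong Allee effect.

## The problem

When a locally extinct species is reintroduced, the release must be large
enough — in density *and* spatial extent — to escape the Allee effect that
dooms small, sparse populations, yet every released individual costs
money. `reintro` is for quantitative ecologists and restoration modellers
who want to ask: *given sex-specific mortality and dispersal rates and a
birth sex ratio, what is the cheapest initial spatial distribution of
females and males that assures restoration of the whole habitat?*

The dynamics is a one-dimensional two-sex reaction–diffusion system for
the female and male occupancy fractions f(x,t), m(x,t):

    ∂f/∂t = D_f ∂²f/∂x² + σ r     f m (1 − f − m) − μ_f f
    ∂m/∂t = D_m ∂²m/∂x² + σ (1−r) f m (1 − f − m) − μ_m m

(mass-action mating, reproduction damped by the unoccupied fraction,
density-independent mortality, diffusive dispersal). Positive equilibria
exist iff A ≡ μ_f/r + μ_m/(1−r) < σ/4; the unstable one is the Allee
threshold. The equilibrium density is maximized at the sex ratio
r\* = √μ_f / (√μ_f + √μ_m). With r = 1/2 and equal rates the system
reduces exactly to a scalar Nagumo-type equation with equilibria
u± = 1/4 ± √(1/16 − μ/σ).

Restoration cost is the number of individuals released — the integral of
the initial densities over space, summed over the sexes. The package
minimizes it three ways and compares them:

1. **Critical nucleus** — the localized unstable stationary profile of
   the scalar reduction (the E = 0 homoclinic orbit of the spatial phase
   plane), truncated at a small density; any upward perturbation
   restores.
2. **Rectangular clusters** — binary search for the critical cluster
   length (or density) using full PDE integrations, with equal or
   sex-specific cluster lengths (nested search plus unit-step descent).
3. **Free shapes** — simulated annealing over per-cell release densities
   under the restoration constraint, checked by a PDE run per accepted
   move.

## A worked example

```r
library(reintro)
p <- model_params(r = 0.5, mu_f = 0.05, mu_m = 0.05)   # canonical set
equilibria(p)
#> Local equilibria of the two-sex dynamics
#>   extinction: (0, 0)  [stable]
#>   Allee (unstable):      f = 0.138197, m = 0.138197  (total 0.276393)
#>   persistence (stable):  f = 0.361803, m = 0.361803  (total 0.723607)

cl <- critical_length(p, dx = 0.25)
cl
#> Critical length: 11.625  (bracket [11.5, 11.75], 10 PDE runs)
cost_rectangular(cl$n_f, cl$n_m, cl$bracket[2])
#> [1] 8.502377

prof <- aperiodic_profile(as_single_sex(p), threshold = 1e-3, dx = 0.05)
prof$cost
#> [1] 10.2686

compare_methods(p, dx = 0.35,
                anneal_cfg = anneal_config(max_stages = 10,
                                           moves_per_stage = 100, seed = 7))
#> Minimum restoration cost by method (ranked)
#>               method    cost   L_f   L_m restores
#>             annealed  8.3332    NA    NA     TRUE
#>    rectangular_equal  8.3577 11.55 11.55     TRUE
#>  rectangular_unequal  8.3577 11.55 11.55     TRUE
#>    aperiodic_nucleus 10.3709 67.20 67.20     TRUE
```

Reading: a release at the persistence-equilibrium densities
(≈ 0.36 per sex) over ≈ 11.6 length units restores the habitat at a cost
of ≈ 8.4 individuals·(unit length); free-shape annealing shaves under 1%
off that; the analytically elegant critical-nucleus release costs ≈ 24%
more because of its long exponential tails. At a biased sex ratio the
ranking changes — sex-specific cluster lengths then beat equal ones
(`optimize_unequal()`), and the advantage grows with the bias.

A thin command-line wrapper for the main operations is installed at
`inst/cli/reintro.R` (subcommands `equilibria`, `optimal-r`, `nucleus`,
`critical-length`, `compare`, `fixtures`).

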
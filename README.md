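# fluxmodules

Characterise and compare the steady-state flux spaces of genome-scale
metabolic models, and extract the reaction modules that distinguish two
growth conditions.

## What it does

A metabolic model under a given condition defines a *flux space* — the
polytope `{v : S v = 0, lb ≤ v ≤ ub}` of all steady-state flux
distributions. Instead of picking one optimal point (as flux balance
analysis does), `fluxmodules` characterises the whole space:

1. **Read** an SBML model (Level 2 or Level 3 + fbc) and **apply**
   condition-specific bounds (blocked uptakes, overrides, release
   reactions).
2. **Preprocess** by flux variability analysis: remove blocked reactions and
   tighten every bound to its achievable range.
3. **Approximate the moments** of the uniform distribution over the polytope
   — deterministically by expectation propagation, or by a hit-and-run
   sampler.
4. **Decompose** the flux covariance by PCA (components up to 99.9%
   cumulative variance), **varimax-rotate** the loadings and extract
   *modules*: reactions loading at least half of each component's maximum.
5. **Score differential flux** per reaction between two conditions with
   `z = (E₂ − E₁)/√(Var₁ + Var₂)` and its two-sided Gaussian probability.
6. **Compare conditions** by bootstrapped independent component analysis of
   the concatenated rotated loadings: an icasso-style stability scan selects
   the number of components, high-replication ICA with a kurtosis filter
   counts how often each rotated component is re-estimated, and a knee-point
   rule selects the condition-specific components.
7. **Export networks**: reaction graphs connected by shared non-currency
   metabolites (byte-stable semicolon tables + GraphML), first-neighbour
   expansion, per-subsystem metabolite–reaction maps.

`run_pipeline()` chains all stages from a YAML or programmatic
configuration, with content-addressed per-stage caching and a JSON manifest
recording parameters, seeds and per-stage timings. See the vignette
(`vignettes/flux-space-comparison.Rmd`) for the methods and numerical
choices.

## Worked example

A toy "triangle" model — one metabolite with an inflow `r1` splitting into
two outflows `r2`, `r3`, all bounded to `[0, 1]`:

```r
library(fluxmodules)

m <- make_triangle_model()
m
#> Metabolic model 'triangle': 3 reactions, 1 metabolites, 3 exchange reactions

sp <- apply_default_bounds(m, condition_label = "open")
sp$model$lb[] <- 0; sp$model$ub[] <- 1
red <- remove_blocked(sp, run_fva(sp))
mom <- ep_moments(red)
round(mom$mean, 4)
#>     r1     r2     r3
#> 0.6667 0.3333 0.3333
round(mom$covariance, 4)
#>        r1      r2      r3
#> r1 0.0545  0.0272  0.0272
#> r2 0.0272  0.0545 -0.0272
#> r3 0.0272 -0.0272  0.0545
```

The means match the analytic values over the triangle polytope
(`E[v1] = 2/3`, `E[v2] = 1/3`) and the covariance reproduces the analytic
anti-correlation of the two branches (`Cov(v2,v3) = −1/36 ≈ −0.0278`).

The comparison stage, demonstrated on the synthetic fixture that plants
three sparse Laplace-weighted source columns (two specific to condition 1,
one to condition 2) among Gaussian filler:

```r
p <- make_planted_loadings()          # deterministic, seed = 1
res <- compare_conditions(p$lm1, p$lm2, seed = 1)
res$optimal_n
#> [1] 3
res$features$selected
#>      column condition component frequency
#> 1 cond1.PC1     cond1         1       200
#> 2 cond1.PC2     cond1         2       200
#> 3 cond2.PC1     cond2         1       200
```

All three planted components — and nothing else — are selected at the knee,
each re-estimated in 200 of 200 final ICA runs, with |correlation| > 0.999
to the ground-truth sources.

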
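# nqdist

Non-quadratic statistical distances for model assessment in R.

When a parametric model `m` is fitted to data generated by an unknown
distribution `τ`, a statistical distance `ρ(τ, m)` measures the cost of the
misspecification. `nqdist` implements the non-quadratic distances that admit
direct probabilistic interpretations, for finite discrete distributions and
for univariate continuous models, and ships the contamination-model Monte
Carlo study that compares them as misspecification measures.

## The distances

**Total variation.** `V(τ, m) = ½ Σ_t |τ(t) − m(t)|` (integral in the
continuous case). `V` is a metric on `[0, 1]` equal to
`sup_A |P_τ(A) − P_m(A)|`: the worst error in probability committed over any
event when `m` is used in place of `τ`. It is convex in both arguments,
insensitive to small perturbations of the density, invariant under monotone
transformations of the variable, and locally equivalent to the Fisher
information: `n^(−1/2) V(m_θ^(n), m_θ0^(n)) ≈ |θ − θ0| √(I(θ0)/2π)` for
nearby parameters.

**Mixture index of fit.** `π*(τ, m) = inf {π : τ = (1 − π) m + π e}` over
arbitrary distributions `e` — the fraction of the population intrinsically
outside the model. Against a fixed discrete model it has the closed form
`π* = sup_t [1 − τ(t)/m(t)]`; against a parametric family it is minimised
over `θ`. The two are linked by `V ≤ π*` and by the W index
`W = V/(1 + V) ∈ [0, ½]`.

**Kullback-Leibler relatives.** `K²(τ, m) = Σ m log(m/τ)` (note the
model-in-front convention used throughout), the likelihood distance
`λ²(τ, m) = Σ τ log(τ/m)`, their symmetric sum (J divergence), and the
Pearson and symmetric chi-squared benchmarks `P²` and `S²`, with the
inequality chain `λ² ≤ P²`, `S² ≤ (64/9) λ²`.

A sample is compared with a continuous model by first smoothing it with a
normal kernel: the total variation between a discrete empirical measure and
any continuous density is identically 1, so the smoothing step is what makes
the comparison informative.

## Worked example

```r
library(nqdist)

tau <- prob_vector(c(0.30, 0.25, 0.20, 0.15, 0.10))
m   <- prob_vector(rep(0.2, 5))
total_variation(tau, m)
#> <distance_result> total_variation = 0.15
pistar_fixed_discrete(tau, m)
#> <pistar_result> pi* = 0.5  (achieved at 4)
w_index(tau, m)
#> [1] 0.1304348
```

The worst event-probability error from using the uniform model is 0.15
(attained at the cell where the model most overshoots, `t = 4`); half the
population would have to be reassigned to an arbitrary "outlier" class
before the uniform model fits the remainder exactly (`π* = 0.5`, driven by
the same cell, where `τ/m = 0.5`); and `W = V/(1+V) = 0.13`.

Continuous case — data from the contamination model
`0.7·N(0,1) + 0.3·N(5,1)` assessed against `N(0,1)`:

```r
set.seed(42)
spec <- contamination_spec(epsilon = 0.3, n = 5000,
                           contaminant = parametric_model("normal", c(5, 1)))
x <- sample_contaminated(spec)
tv_sample_model(x, parametric_model("normal", c(0, 1)))
#> <distance_result> tv_sample_model = 0.2968827
#>   bandwidth: 0.2196
pistar_family(x, seed = 1)
#> <pistar_result> pi* = 0.32206  (achieved at -0.72611)
#>   theta_hat: -0.015721,  1.005173
```

The smoothed total variation is close to the population value
`0.3 · V(N(0,1), N(5,1)) ≈ 0.296`, and the family-minimised mixture index
estimates a contamination fraction near the true `ε = 0.3`, with the best
normal component essentially `N(0, 1)`.

`run_study()` runs the full Monte Carlo grid (contaminants × ε × n ×
measures) and returns a tidy summary table; a small command-line interface
(`inst/scripts/nqdist`) exposes the same operations on CSV/JSON files, e.g.
`nqdist dist --measure tv --tau tau.csv --m model.csv`.

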
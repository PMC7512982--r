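---
title: "Non-quadratic distances for model assessment: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-quadratic distances for model assessment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nqdist)
```

This vignette is the package's account of the statistics it implements and
of the design choices made where the methods leave genuine freedom. The
setting is model assessment: data arise from an unknown distribution $\tau$,
a parametric model $m_\theta$ is proposed, and a statistical distance
$\rho(\tau, m)$ — nonnegative, zero when the two distributions are
equivalent for the statistical purpose at hand, not necessarily symmetric —
quantifies the misspecification cost.

## Discrete distances and their conventions

On a finite support the package provides total variation, squared Hellinger,
affinity/Matusita, Kullback-Leibler, likelihood, J-divergence, and the
Pearson and symmetric chi-squared benchmarks. Two conventions apply
throughout and are worth stating once:

* **Zero cells.** All log-type distances use $0 \log(0/x) = 0$ and
  $x \log(x/0) = +\infty$ for $x > 0$; an infinite distance is returned as a
  value, never raised as an error, because mass observed on a cell the model
  declares impossible is informative, not exceptional. $0/0$ cells of the
  symmetric chi-squared contribute zero (both distributions agree there).
* **Kullback-Leibler direction.** $K^2(\tau, m) = \sum_t m(t)\log(m(t)/\tau(t))$
  puts the *model* in front of the logarithm. This is the reverse of the most
  common convention; the likelihood distance
  $\lambda^2(\tau, m) = \sum_t \tau(t)\log(\tau(t)/m(t))$ is the familiar
  direction, and their sum is the symmetric J divergence. Published
  Kullback-Leibler values computed by other software may correspond to either
  direction, so numeric comparisons across implementations are meaningful
  only when the direction and the discretisation are both known.

Validation is deliberately strict: probability vectors must sum to one within
$10^{-12}$ and are renormalised only on explicit request, since silent
renormalisation would mask upstream data errors.

One inequality needs a correction relative to a form sometimes quoted. With
affinity $\rho = \sum\sqrt{\tau m}$ and Matusita distance
$M = [\sum(\sqrt{\tau}-\sqrt{m})^2]^{1/2}$, the identity $M^2 = 2(1-\rho)$
holds, but $2(1-\rho) \le V$ does **not** (mutually singular pairs give
$2(1-\rho) = 2 > 1 \ge V$). The provable chain, which the tests assert, is
$$ 1-\rho \;=\; H^2 \;\le\; V \;\le\; \sqrt{2}\,M, $$
with the lower bound from the Hellinger sandwich
$H^2 \le V \le [H^2(2-H^2)]^{1/2}$ and the upper from Cauchy–Schwarz.

### Oracles

Two closed forms are paired with brute-force oracles used in the test suite:
the event-supremum form of total variation (`tv_set_supremum()`, full subset
enumeration, capped at 20 support points) and a feasibility scan for the
mixture index (`pistar_oracle()`, coarse-to-fine grid on $\pi$ at $10^{-6}$
resolution). The oracles only use the defining property of each quantity, so
agreement with the closed forms is a genuine cross-check rather than a
tautology.

## Comparing a sample with a continuous model

The empirical measure of a sample is discrete, and the total variation
between a discrete and a continuous measure is identically 1. The package
therefore smooths the sample with a normal kernel before comparing
(`tv_sample_model()`), which is the "discretization robustness" route; the
degenerate alternative is demonstrated in the tests by discretising a
continuous density ever more finely against a two-atom empirical measure and
watching the distance climb to 1.

**Bandwidth.** The default selector is the Sheather–Jones solve-the-equation
plug-in (`bw_sheather_jones()`), with Silverman's normal-reference rule
$0.9\min(s,\mathrm{IQR}/1.349)n^{-1/5}$ available explicitly and used as a
fallback when the plug-in equation has no solution (tiny or nearly-discrete
samples). The choice matters: normal-reference rules take their scale from
the overall standard deviation, so for a well-separated bimodal sample such
as $0.5N(0,1) + 0.5N(10,1)$ at $n = 5000$ they give $h \approx 0.8$ and
oversmooth each unit-variance component, biasing the total variation
against $N(0,1)$ upward beyond the study's own tolerance; the plug-in
adapts to the local structure ($h \approx 0.25$) and leaves the estimate
within Monte Carlo noise of the analytic mixture-versus-model value (the
table-cell checks in the test suite exercise exactly this). Both rules
agree for unimodal samples.
The bandwidth is always recorded in the result's `meta`.

**Quadrature.** $\tfrac12\int|f-g|$ is computed by composite trapezoid rule
on an equispaced grid — by default 4096 points spanning the sample range and
the $10^{-8}$ model quantiles, padded by five bandwidths. The integrand has
kinks where the densities cross, which defeats high-order rules but costs the
trapezoid rule only $O(h^2)$ per kink; at the default spacing the quadrature
error is of order $10^{-5}$, and a denser grid (the tests use up to $2^{15}$
points for the closed-form checks at $10^{-6}$) removes it entirely. The
amount of density mass the grid captures is reported, with a diagnostic flag
when more than $10^{-6}$ is missed.

**Grid evaluation.** On equispaced grids the kernel estimate is evaluated
through `stats::density()` (FFT with linear binning), which computes the same
normal-kernel average as the definitional evaluator `predict.kde()` to well
below quadrature tolerance (asserted in the tests); the exact evaluator is
used where grids are small or non-equispaced, as in the continuous mixture
index.

**Two-sample Kullback-Leibler.** `kl_sample_sample()` bins both samples on a
common 100-bin equal-width grid over the pooled range and applies additive
smoothing of $\alpha = 1/2$ per bin before normalising, so the estimate is
always finite; the model-side sample is placed in front of the logarithm,
matching the discrete convention above. A consequence of that direction is
worth knowing: when the data contain a component the model-side sample never
visits, the estimate is governed by $\log 1/(1-\varepsilon)$ rather than by
the separation, so it orders contaminants correctly but compresses their
magnitudes; the reverse direction explodes with separation instead. This is
why cross-implementation numeric comparisons of two-sample KL values are not
meaningful without the binning and direction conventions, and why the study
below treats the KL column qualitatively.

**Fisher local equivalence.** The scaled product-measure total variation
$n^{-1/2}V(m_\theta^{(n)}, m_{\theta_0}^{(n)})$ approaches
$|\theta-\theta_0|\sqrt{I(\theta_0)/2\pi}$, and `fisher_local_tv()` estimates
it by Monte Carlo via $V(P,Q) = \tfrac12 E_P|1 - q(X)/p(X)|$ on i.i.d.
blocks ($n$-dimensional quadrature being infeasible). The equivalence is
*local*: writing $a = \sqrt{n}\,|\theta-\theta_0|\sqrt{I}$, the exact scaled
value behaves like $|\theta-\theta_0|\sqrt{I}\,[2\Phi(a/2)-1]/a$, which
matches the limit to under 1% for $a \le 0.5$ but halves it already at
$a = 5$ — at fixed separation and growing $n$ the scaled quantity must decay
to zero, since $V \le 1$. The tests therefore evaluate the estimator in the
local regime (e.g. $\theta - \theta_0 = 0.003$ at $n = 10^4$) and compare
within three Monte Carlo standard errors.

## The mixture index of fit

Discrete case: $\pi^*(\tau,m) = \sup_t[1-\tau(t)/m(t)]$, with the residual
distribution $e^*(t) = [\tau(t) - (1-\pi^*)m(t)]/\pi^*$ reconstructing
$\tau = (1-\pi^*)m + \pi^* e^*$ exactly and touching zero at the achieving
cell (ties report the smallest support point). Two structural facts shape
its use, and both are encoded as tests: $V \le \pi^*$, and $\pi^*$ is
*one-sided and non-robust* — moving a sliver $\delta$ of mass off a cell
where $m(t) = \delta$ sends $\pi^*$ to 1 while $V$ moves by $\delta/2$.

Continuous case: the same supremum over a kernel density estimate, with two
restrictions that any usable continuous version must make, because a
lighter-tailed estimate gives $1 - \hat\tau(t)/m(t) \to 1$ in the tails
("light tails read as 100% outliers"):

* the grid covers only the observed data range $[\min x, \max x]$
  (512 points by default), and
* grid points where $\hat\tau$ falls below a floor — by default 1% of its
  maximum — are dropped, so the supremum is taken where the density estimate
  actually carries information.

The supremum over the remaining noisy ratio is still biased upward for small
contamination fractions (floor-level cells carry relative kernel noise of
order $[nh\hat\tau]^{-1/2}$, easily 25–30% at moderate $n$), a bias visible
in the study results below and inherent to this estimator class, not a
tuning failure.

**Family minimisation.** $\pi^*(\tau, \mathcal{M})$ minimises the fixed-model
index over a normal family, parameterised as $(\mu, \log\sigma)$ to keep the
scale positive, by Nelder–Mead simplex search. The objective — a maximum of
ratios — is non-smooth and multimodal: for a well-separated bimodal sample
there is a spurious basin in which a very wide normal dominates the kernel
estimate on every retained grid point, driving the objective toward zero
precisely because the floor has discarded the valley between the modes where
such a model is falsified. The conventional starting model $(0, 1)$ sits in
the basin that fits the main component, and the search is kept there
deliberately: restarts (5 by default) jitter the start only mildly
($\mathrm{sd}=0.25$ on both coordinates). The reported index is thus the
local minimum reachable from the declared starting model, which is the
convention under which the study's reference values are defined; `meta$converged`
flags simplex non-convergence, and the best value found is still returned.

## The contamination study

The generator draws from $(1-\varepsilon)N(0,1) + \varepsilon\,c$ with
contaminant $c$ either $N(\mu, 1)$ (asymmetric, $\mu \in \{1,5,10\}$) or
$N(0, \sigma^2)$ (symmetric, $\sigma^2 \in \{4,9,16\}$). Composition is
deterministic — exactly $\mathrm{round}(n\varepsilon)$ contaminant draws,
then a shuffle — matching the stated design in which $n\varepsilon$ of the
sample comes from the contaminant (the grids make $n\varepsilon$ integral),
rather than binomial mixing. Full-scale conditions are 500 replications at
$n \in \{200, 1000, 5000\}$.

Per replication the study computes the smoothed total variation against
$N(0,1)$, the two-sample Kullback-Leibler against a freshly drawn $N(0,1)$
sample of the same size (fresh per replication, which is what keeps the KL
column's replication variance honest), and — for asymmetric contaminants
only, since the index presumes a heterogeneous two-class population — the
family-minimised mixture index started at $(0,1)$. Every cell derives an
independent random stream from the master seed by stable hashing of its
coordinates, so results are reproducible and independent of cell evaluation
order; failed replications are counted per cell rather than silently
dropped, and standard deviations use the $n-1$ denominator.

**Problem sizes.** The package's own verification runs the study scaled
down: the distribution-level checks use the full 200-to-1000-pair random
suites, the table-level checks use 100 replications at $n = 5000$ for the
reference cells (tolerances widened from $\pm 0.01$ to $\pm 0.015$ for total
variation accordingly, $\pm 0.03$ for the mixture index), and the
qualitative pattern checks use 25 replications at $n = 1000$ across the full
contaminant grid. These sizes were chosen once as the smallest at which
Monte Carlo error is comfortably below the tolerances.

**What the generator does and does not emulate.** Samples are exact i.i.d.
draws from clean two-component normal mixtures. Real data bring features the
study deliberately excludes — dependence, heavier-than-normal tails,
measurement rounding, contamination that is itself structured — so passing
the study's checks demonstrates correctness of the estimators under the
stated mixture conditions, not robustness of the conclusions to arbitrary
real-world misspecification.

## Known limitations

* Everything continuous is univariate; transformation invariance has no
  natural multivariate analogue here and none is attempted.
* Small-contamination cells ($\varepsilon \le 0.05$) of the smoothed total
  variation are dominated by kernel bias/variance rather than by the signal,
  and the continuous mixture index overestimates small $\varepsilon$ (floor
  noise) while severely underestimating it for overlapping contaminants such
  as $N(1,1)$, where the sample is effectively unimodal — the study's
  qualitative checks encode both failure modes.
* No hypothesis-test p-values or bootstrap confidence limits are provided
  for any distance; the package measures misspecification, it does not test
  it.
* Two-sample Kullback-Leibler values are comparable only within this
  package's binning and direction conventions.
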
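---
title: "General Bayesian updating under alternative divergences: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{General Bayesian updating under alternative divergences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divbayes)
```

## The inferential model

In the M-open world no member of the fitted class `f(.; theta)` equals the
data generating density `g`, so "the true parameter" is undefined.  What
remains well defined is the divergence-minimising parameter
`theta* = argmin_theta d(g, f(.; theta))` for a divergence `d` the analyst
chooses.  Standard Bayesian updating is the special case `d = KL`: the
posterior concentrates on the KL-minimising parameter, which is exactly why
it is sensitive to tail misspecification — the logarithmic score is
unbounded, so a handful of surprising observations can dominate the fit.

The general Bayesian (Gibbs) posterior replaces the log-likelihood by any
per-observation loss whose expectation under `g` is minimised at `theta*`:

    pi_d(theta | x)  ~  pi(theta) * exp( - w * sum_i l_d(x_i, f(.; theta)) )

with calibration weight `w`.  `divbayes` implements the canonical losses of
six divergence families:

| divergence | per-observation loss | needs `g_n`? |
|---|---|---|
| KL | `-log f(x)` | no |
| total variation | `(1/2) |1 - f(x)/g_n(x)|` | yes |
| Hellinger | `-sqrt(f(x)/g_n(x))` | yes |
| alpha, `a` in (0,1) | `-(1/(a(1-a))) g_n(x)^(a-1) f(x)^(1-a)` | yes |
| density power, `a > 0` | `-(1/a) f(x)^a + (1/(1+a)) int f^(1+a)` | no |
| alpha-beta | `-(1/(ab)) g_n^(a-1) f^b + (1/(a(a+b))) int f^(a+b)` | yes |

The density-based losses replace the unknown `g` by a kernel density
estimate `g_n`, so the update is conditional on that estimate as well as on
the data; as `g_n` is consistent for `g`, the empirical loss converges to
the exact score of the divergence.  The density power divergence avoids
`g_n` entirely at the cost of the model power integral, which is closed
form for the Gaussian families used here:
`int N(mu, s^2)^(1+a) = (2 pi s^2)^(-a/2) (1+a)^(-1/2)`.

The S-Hellinger sub-family (`alpha = beta = (1+alpha_s)/2`) is exposed as a
functional only, for identity and limit checks; its two implicit
hyperparameters trade off against each other without offering anything the
alpha and power families do not, so no posterior target is provided for it.

### The TV loss and an ambiguity in its printed form

Written without an absolute value the TV score `(1/2)(1 - f/g_n)` has
expectation identically zero under `g_n`, which cannot equal the
TV-divergence up to an entropy term.  The implementation therefore uses
`(1/2)|1 - f/g_n|`, the unique reading whose expectation under `g`
recovers the TV functional.  A consequence worth knowing: the loss is not
monotone in the predicted probability — over-prediction (`f > g_n`) is
penalised exactly like under-prediction, and the loss is bounded by `1/2`
throughout the tails (`f -> 0`), which is what makes posterior tails
prior-driven under this score.  The ratio `f/g_n` is clipped below via a
density floor on `g_n` (default `1e-12`, `options(divbayes.density_floor=)`)
so an extreme observation with vanishing estimated density cannot produce
an undefined ratio.

### A normalisation wrinkle in the S-Hellinger family

With the squared Hellinger defined as `(1/2) int (sqrt g - sqrt f)^2`
(the convention used throughout this package, and the one under which the
sandwich `dH2 <= dTV <= sqrt(dH2 (2 - dH2))` holds), the S-Hellinger
functional at `alpha_s = 0` evaluates to *four* times the squared
Hellinger — equivalently, twice the no-half-convention squared Hellinger.
Both the printed prefactor `2/(1+alpha_s)` and the alpha-beta substitution
agree on this, so the functional is implemented as printed and the tests
assert the factor-4 identity explicitly.

## Calibration weight

`w = 1` throughout (and as the default).  Because every loss here is the
canonical form of a well-defined divergence applied to a proper model, the
loss is on the likelihood's natural scale — the KL case with `w = 1` *is*
Bayes' rule — so no further calibration is warranted.  The weight is still
a field of `divergence_spec()` for sensitivity analyses.

## Density estimation choices

* **Marginal `g_n`** — fixed-width Gaussian-kernel KDE.  The bandwidth rule
  is Silverman's `1.06 min(sd, IQR/1.34) n^(-1/5)` by default; robustness
  results are bandwidth-sensitive, so the bandwidth is an explicit argument
  everywhere.  Evaluation at a sample point includes that point's own
  kernel (the plain fixed-width estimate); a leave-one-out variant is
  available behind a flag for sensitivity analysis.
* **Conditional `g_n(y | x)`** — Nadaraya–Watson form
  `sum_i w_i(x) K_hy(y - y_i)` with product-kernel weights, which
  integrates to one in `y` for every `x` by construction.  Bandwidths come
  from a two-stage rule: normal-reference bandwidths per coordinate, then a
  least-squares cross-validation refinement of the response bandwidth over
  a multiplier grid (0.4–2.4) with the covariate bandwidths held fixed.
  The two-stage structure follows standard conditional-KDE practice; the
  exact selector behind the original studies is not recoverable, and the
  acceptance tolerances of the reproduction studies absorb this.
* Weights are computed in log space and normalised per evaluation point, so
  distant covariates cannot underflow to an all-zero weight vector.

What the KDE does *not* emulate: adaptive/variable-width bandwidths, and
the known difficulty of fixed-width estimates in capturing heavy tails
without over-smoothing the centre.  Passing tests therefore demonstrate
correct behaviour for low-dimensional, moderately heavy-tailed data; they
say nothing about KDE quality in high dimensions, where all density-based
losses here inherit the usual curse of dimensionality.

## Sampling

The sampler is an adaptive Gaussian random-walk Metropolis on an
unconstrained parameterisation (`log sigma` with the Jacobian added; raw
coefficients).  During burn-in the global proposal scale follows a
Robbins–Monro recursion toward 25% acceptance and the proposal covariance
is refreshed every 200 iterations from the accumulated history; both are
frozen afterwards, so the post-burn-in chain is a fixed-kernel Metropolis
chain and exactly reproducible from its seed.  Defaults are 20,000
iterations with 5,000 burn-in; the experiment runners use 8,000/3,000,
which for these 2–21 parameter targets leaves Monte-Carlo error an order
of magnitude below the tolerances being tested.  A NaN log-target aborts
with the offending parameter value; `-Inf` is treated as rejection.

Standard (KL) updating of the Gaussian linear models is conjugate
normal–inverse-gamma, and the experiment runners use the closed form for
the KL column by default (with exact NIG draws when predictive variances
are needed); the MCMC-versus-conjugate agreement is itself a test.

Initialisation is deterministic (least squares for the coefficients, the
residual standard deviation for the scale), so chains are reproducible
without a warm-up search.

## The simulators and what the studies mean

* **epsilon-contamination** `0.99 N(0,1) + 0.01 N(5, 5^2)`: a small, remote
  contamination that the KL fit must chase (variance inflation toward the
  mixture variance 1.4875) while bounded-score divergences may ignore it.
* **Student-t(4)**: consistently heavy tails rather than point
  contamination.
* **Heteroscedastic regression** `y = X beta + exp(2 X1 / 3) z`,
  `X ~ N_p(0, I)`, `beta_i ~ Unif(-2, 2)` drawn once per study and held
  fixed across the `N = 50` repeats; the homoscedastic Gaussian linear
  model is wrong in its variance function, with marginal error variance
  `exp(8/9) ~ 2.43`.  Test sets are 100 fresh rows with exactly noiseless
  responses, so test MSE isolates mean-function recovery.  The per-repeat
  sum over the 100 test points is averaged over repeats but deliberately
  not divided by 100 (all methods are rescaled equally).
* **AR(L) + GARCH(1,1)** `y_t = x_t + e_t`: the AR signal is observed
  through conditionally heteroscedastic noise; an AR model with a constant
  innovation variance is fitted anyway.  The AR innovation standard
  deviation is 1 by default (configurable) — the generating value behind
  the original study is not stated, and under a correctly specified model
  the one-step RMSE is innovation-dominated, so this choice directly sets
  that baseline (~1 here).  The high-volatility setting
  `omega = 2, alpha1 = 0.99, beta1 = 0.01` sits exactly on the integrated
  boundary `alpha1 + beta1 = 1`: no stationary variance exists, sample
  second moments of `e` are heavy-tailed across seeds, and any summary
  built on them (fitted KL variance, predictive variance) is strongly
  seed-dependent.  The GARCH state starts at the stationary variance when
  it exists and at `omega` on the boundary, with a 500-step burn-in
  discarded.  The test block continues the *latent* AR process (innovations
  included, observation error excluded); one-step predictions condition on
  the observed test history — lags are previous test values, never
  previous predictions.

Posterior-mean variances under non-KL divergences are variances of the
divergence-optimal predictive, not estimates of the response variance; the
regression study reports them in exactly that spirit.

## Influence diagnostics

The leave-one-out influence of observation `i` is the Hellinger distance
between Gaussian approximations of the full-data and leave-one-out
posteriors, taken on the unconstrained sampling scale.  The approximation
is Laplace by default (deterministic, fast — the diagnostic is a shape
check, not an inferential quantity) with an MCMC moment-matching
alternative.  For density-based divergences the KDE is refitted without
observation `i` by default; the full-sample bandwidth is held fixed so the
refit is an exact O(n) kernel-matrix update, and a flag freezes `g_n`
entirely.  Influence is evaluated on a quantile-stratified subset (default
100 points) to keep curves affordable.  The characteristic shapes — strictly
increasing influence in outlyingness under KL, rise-then-fall under the
robust divergences, visible once observations pass roughly 3–4 scale units
from the centre — are asserted as binned isotonic patterns.

## Numerical choices

* Divergence functionals use adaptive quadrature (`rel.tol = 1e-8`) on a
  stated finite support, with a normalisation precondition (`int = 1`
  within `1e-3`) that turns mis-specified supports into errors rather than
  silent nonsense; bivariate densities use tensor trapezoid grids and are
  intended for diagnostics, not inference.
* The Gaussian power integral's closed form is verified against quadrature
  to `1e-8` over a `(sigma, alpha)` grid.
* The KL loss at `f = 0` is `+Inf` by default (MCMC rejection), with an
  optional finite cap.
* Degenerate inputs fail loudly: constant samples (no bandwidth), explosive
  AR polynomials, non-positive GARCH `omega`, missing density estimates,
  out-of-range hyperparameters.

## Problem sizes used by the reproduction suites

The studies are run at their stated scale: `N = 50` repeats of `n = 200`
for the regression tables (p = 1 and p = 20), `T = 1000` with a 100-point
test continuation for the three time-series presets, `n = 1000` / 200 for
the simple-inference generators, and 1000 t(4) draws with a 100-point
stratified subset for the influence curves.  The KL columns go through the
conjugate closed form; everything else is MCMC at 8,000 iterations.

## Known limitations

* Bounded-score posteriors inherit their tails from the prior; with a
  deliberately remote tight prior the data term (bounded by `n/2` for TV)
  cannot overcome it.  This is a feature of the theory, reproduced by a
  test, but it means prior elicitation matters more than under KL.
* The minimum-DPD estimator with `alpha = 0.5` is markedly more efficient
  than least squares under the heteroscedastic design (it approaches the
  GLS weighting implicitly); its coefficient and test errors here are
  several-fold smaller than under KL, and smaller than some published
  figures for comparable set-ups whose samplers or density estimates spread
  the posterior mean more.  The package reports what the loss as defined
  produces.
* Only conditionally Gaussian model families ship; the posterior builder
  is family-agnostic in its interfaces (losses take densities and a power
  integral), so adding a family means supplying those two ingredients.
* Multivariate responses, adaptive KDEs, calibration-weight selection
  (`w != 1`) and model selection across families are out of scope.
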
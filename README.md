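# divbayes

Robust Bayesian inference for misspecified models by **general Bayesian
minimum-divergence updating**.

## The problem

When every candidate model `f(·; θ)` is acknowledged to be wrong (the
*M-open* world), there is no "true" parameter to learn; the coherent target
is the parameter minimising a statistical divergence between the model and
the data generating density `g`,

&nbsp;&nbsp;&nbsp;&nbsp;θ\* = argmin<sub>θ</sub> d(g, f(·; θ)).

Standard Bayes is the `d = KL` case, and the unbounded logarithmic score
behind it makes the fit hostage to the tails: a 1% contamination or a
heavy-tailed error distribution drags the whole posterior.  The general
Bayesian (Gibbs) posterior

&nbsp;&nbsp;&nbsp;&nbsp;π<sub>d</sub>(θ | x) ∝ π(θ) exp( −w Σ<sub>i</sub> ℓ<sub>d</sub>(x<sub>i</sub>, f(·; θ)) ),&nbsp;&nbsp;w = 1,

is a principled belief update for *any* divergence with a per-observation
score ℓ<sub>d</sub>.  `divbayes` implements the canonical losses for the
Kullback–Leibler, total-variation, Hellinger, alpha (α ∈ (0,1)),
density-power (β/DPD, α > 0) and two-parameter αβ divergence families —
with the kernel density estimates g<sub>n</sub> that the TV/Hellinger/alpha/αβ
empirical losses require (marginal and conditional), a Gaussian closed-form
power integral for DPD, an adaptive random-walk Metropolis sampler,
conjugate normal–inverse-gamma shortcuts for the KL case, leave-one-out
posterior influence diagnostics, and seeded simulators plus runners for
three misspecification studies (ε-contamination, heteroscedastic
regression, AR fits to GARCH-corrupted series).

It is for statisticians and quantitative scientists who want to keep an
interpretable parametric model but decouple *what they believe* from *how
severely tail misspecification is punished*.

## Worked example

Fit a normal model to 1000 draws from the ε-contaminated mixture
`0.99 N(0,1) + 0.01 N(5,5²)` under standard (KL) updating and under the
density-power divergence with α = 0.5:

```r
library(divbayes)

ds  <- simulate_contaminated_normal(n = 1000, seed = 1)
est <- fit_kde(ds$data)                     # g_n for density-based losses

fits <- lapply(list(kl    = divergence_spec("kl"),
                    power = divergence_spec("dpd", alpha = 0.5)),
  function(dv) {
    post <- build_general_posterior(prior_location_scale(), gaussian_model(),
                                    dv, ds, density_estimate = est)
    summary(sample_posterior(post, n_iter = 8000, burn_in = 3000, seed = 2))
  })

fits$kl
#>   parameter   mean     sd ess
#> 1        mu 0.0379 0.0400 479
#> 2     sigma 1.2049 0.0271 517

fits$power
#>   parameter    mean     sd ess
#> 1        mu -0.0285 0.0608 493
#> 2     sigma  1.0542 0.0473 578
```

The KL posterior inflates σ to 1.20 to chase the 1% contamination at
x = 5 (the mixture standard deviation is √1.4875 ≈ 1.22); the
power-divergence posterior sits at σ ≈ 1.05, describing the 99% bulk.
That is the entire point: same prior, same model, different divergence
target, and the robust update ignores what the analyst asked it to ignore.

The three studies are one call each, e.g.

```r
run_regression_experiment(p = 1, n_repeats = 50,
                          divergences = c("kl", "hellinger", "power"))
run_timeseries_experiment("garch_high", divergences = c("kl", "hellinger"))
```

and a thin CLI wraps the same functions
(`inst/cli/divbayes simulate|fit|influence|experiment ...`).

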
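# loobound

Bounded evidence from Bayesian leave-one-out cross-validation.

## The problem

Bayesian leave-one-out cross-validation (LOO) scores a model by the sum of
log leave-one-out predictive densities,

    elpd_loo = sum_i log p(y_i | y_-i),
    p(y_i | y_-i) = integral p(y_i | theta) p(theta | y_-i) dtheta,

and two models are compared through the pseudo-Bayes factor
`PSBF_01 = exp(Delta elpd)` or the softmax model weights
`w_m = exp(elpd_m) / sum_j exp(elpd_j)`. LOO is widely used to adjudicate
between models of cognition and behavior, and is often treated as a safe
default. This package makes one of its failure modes concrete and
reproducible: when the data are *perfectly* consistent with a simple
point-null "general law", LOO's support for that law does **not** grow
without bound. It converges to a fixed, modest ceiling, can depend on the
prior of the rival model even asymptotically, and can even *decline* as
law-consistent observations accumulate.

Three conjugate comparisons, each fully closed-form, exhibit this:

| Example | Null (general law) | Alternative | Idealized data | Limit of Δelpd |
|---|---|---|---|---|
| induction | Bernoulli θ = 1 | θ ~ Beta(a, b) | n successes | **b** (prior-dependent) |
| chance | Bernoulli θ = 1/2 | θ ~ Beta(a, b) | k = n/2 successes | 1 |
| normal mean | μ = 0, σ² = 1 known | μ ~ N(0, σ₀²) | ȳ = 0, s² = 1 exactly | 1 |

So for the chance and normal-mean tests the asymptotic null-model weight is
`e/(1+e) ≈ 0.731` no matter the prior, while the ordinary Bayes factor on the
same data grows without bound (e.g. `BF01 = n + 1` for the induction example
under a uniform prior). For some priors (Beta(0.5, 0.5) in examples 1–2,
N(0, 3²) in example 3) the weight approaches its ceiling *from above*, and for
others (Beta(1, 5); N(0, 2.035²)) the trajectory is nonmonotone.

## What the package provides

* **Datasets**: generators for the three idealized regimes
  (`make_all_successes()`, `make_half_successes()`,
  `make_standardized_normal()`), noisy sampling (`sample_from_model()`), and
  one-value-per-line file I/O (`read_outcomes()`, `write_outcomes()`).
* **LOO engine**: analytic per-observation leave-one-out predictives for both
  conjugate families (`elpd_loo()`, `loo_pred_bernoulli()`,
  `loo_pred_normal()`) plus an independent quadrature oracle
  (`loo_numeric_oracle()`) that integrates likelihood × leave-one-out
  posterior directly.
* **Comparison metrics**: `psbf()`, `loo_weights()` (log-sum-exp stable),
  `loo_compare()`, and the marginal-likelihood `bayes_factor()` for contrast.
* **Closed forms and limits**: `delta_elpd_*()` for each example, stable out
  to n = 10¹² via `log1p`, and `loo_limits()` for the analytic asymptotes.
* **Trajectories**: `weight_trajectory()`, `classify_shape()`,
  `find_interior_extremum()`, `figure_data()` and a base-graphics `plot()`
  method reproducing the weight-versus-n curves.
* **CLI**: `inst/cli/loobound` with subcommands `generate`, `loo`, `compare`,
  `limits`, `trajectory`, `figure` (see `?loo_cli`).

## Worked example

One hundred Bernoulli observations, exactly half successes — data that could
not agree better with the chance hypothesis θ = 1/2:

```r
library(loobound)
cmp <- loo_compare(point_null("bernoulli", 0.5), beta_prior(1, 1),
                   make_half_successes(100))
cmp
#> LOO comparison on n = 100 observations (analytic predictives)
#>   H0: theta = 0.5  [bernoulli family]
#>   H1: theta ~ Beta(1, 1)  [Bernoulli family]
#>   elpd_loo:  H0 = -69.3147,  H1 = -70.3098
#>   Delta elpd = 0.995033   PSBF01 = 2.70481   w0 = 0.730081   w1 = 0.269919
#>   (marginal-likelihood Bayes factor BF01 = 8.03851)
```

The LOO weight on the true null is 0.73 — already essentially at its
asymptotic ceiling `e/(1+e)`, and it will never exceed it — while the Bayes
factor (8.0 here) keeps growing with n. The full trajectory and its shape:

```r
tr <- weight_trajectory("chance", beta_prior(1, 5))
tr
#> LOO weight trajectory (chance example), 260 sample sizes in [2, 1e+06]
#>   prior: H1: theta ~ Beta(1, 5)  [Bernoulli family]
#>   shape: nonmonotone;  asymptote w0 = 0.731059;  final w0 = 0.731059
plot(tr)   # weight vs n, dotted line at the asymptote
```

Under this prior the support for the chance law first rises, then falls back
toward 0.731: more perfectly-consistent data can mean *less* apparent
support. In the normal-mean example the stationary point can be located
explicitly:

```r
find_interior_extremum("normal_mean", normal_mean_prior(2.035^2))
#> [1] 5.985521
```

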
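---
title: "Bounded LOO evidence for a true point null: models, numerics, design"
author: "loobound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounded LOO evidence for a true point null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loobound)
```

## The inferential setting

Leave-one-out cross-validation in its Bayesian form (LOO) evaluates a model
by how well the posterior built from all observations but one predicts the
held-out one:

$$\mathrm{elpd}_{\mathrm{loo}} = \sum_{i=1}^n \log p(y_i \mid y_{-i}),
\qquad
p(y_i \mid y_{-i}) = \int p(y_i \mid \theta)\, p(\theta \mid y_{-i})\,
\mathrm{d}\theta.$$

Two models are compared through the difference of their elpd estimates: the
pseudo-Bayes factor $\mathrm{PSBF}_{01} = \exp(\Delta\mathrm{elpd})$, or the
two-model weight $w_0 = \mathrm{PSBF}_{01}/(1+\mathrm{PSBF}_{01})$, the
logistic transform of $\Delta\mathrm{elpd}$.

This package studies what these quantities do when a *point null* is exactly
true — i.e. when there exists arbitrarily much data perfectly consistent with
a "general law" — in three settings chosen so that every posterior,
predictive and limit is available in closed form:

1. **Induction.** $H_0:\theta = 1$ versus $H_1:\theta\sim\mathrm{Beta}(a,b)$
   for Bernoulli data consisting solely of successes. The leave-one-out
   posterior under $H_1$ is $\mathrm{Beta}(a+n-1,\,b)$ and the predictive
   probability of the held-out success is the generalized rule of succession
   $(a+n-1)/(a+n-1+b)$, so
   $\Delta\mathrm{elpd}(n) = -n\log\frac{a+n-1}{a+n-1+b} \to b$.
   The bound is *prior-dependent even asymptotically*: the weight ceiling is
   $e^b/(1+e^b)$.
2. **Chance.** $H_0:\theta = 1/2$ versus the same Beta alternative, with even
   $n$ and exactly $n/2$ successes. Here
   $\Delta\mathrm{elpd}(n) = \frac n2\log\frac{a+b+n-1}{2a+n-2} +
   \frac n2\log\frac{a+b+n-1}{2b+n-2} \to 1$, independent of $(a,b)$: the
   ceiling is $w_0 = e/(1+e) \approx 0.731$.
3. **Normal mean.** $H_0:\mu = 0$ versus $H_1:\mu\sim N(0,\sigma_0^2)$ with
   known unit observation variance, for data whose sample mean is exactly 0
   and sample variance (with $n-1$ denominator) exactly 1. The leave-one-out
   predictive is $N(\mu_{-i},\,1+\sigma^2_{-i})$ with
   $\mu_{-i} = (n-1)\bar y_{-i}/(n-1+\sigma_0^{-2})$ and
   $\sigma^2_{-i} = 1/(n-1+\sigma_0^{-2})$, and again
   $\Delta\mathrm{elpd}(n)\to 1$.

The contrast object is the ordinary marginal-likelihood Bayes factor, which
on the same data grows without bound (`bayes_factor()`; e.g. $BF_{01}=n+1$
for induction under a uniform prior, $\sqrt{1+n\sigma_0^2}$ for the exactly
standardized normal data). A maximum-likelihood version of LOO is even worse
off in the induction case: every training fold estimates $\hat\theta = 1$,
both models predict the held-out success with probability one, and the data
are completely uninformative (`mle_loo_induction()` returns 0 for every n).

## What the synthetic regimes emulate — and what they do not

The generators produce the *idealized* datasets these results are about:

* `make_all_successes(n)` — n confirmatory instances;
* `make_half_successes(n)` — even n with exactly n/2 successes, laid out
  deterministically as 1, 0, 1, 0, …; the layout is immaterial because every
  Bernoulli leave-one-out predictive depends on the data only through the
  total success count and the held-out value (tested as an invariant);
* `make_standardized_normal(n, seed)` — standard-normal draws affinely
  rescaled so $\bar y = 0$ and $s^2 = 1$ hold to machine precision, matching
  the $n-1$ variance convention above. For $n = 2$ this forces the pair
  $(\pm 1/\sqrt2)$ regardless of seed.

`sample_from_model()` adds genuinely stochastic variants for property tests.
All stochastic generators take a mandatory explicit seed and restore the
caller's RNG state: no hidden global state.

These regimes are a deliberate best case for the null, not a model of real
data. Real samples from a true null fluctuate around $k=n/2$ or $\bar y = 0$,
so observed trajectories wobble around the deterministic curves computed
here; the *bounds* are unchanged, but monotonicity statements apply to the
idealized curves only. Passing tests therefore demonstrate properties of the
method on law-consistent data, not predictions for any particular noisy
dataset.

## Numerical choices

* **Stability at large n.** Every closed form contains terms like
  $n\log\frac{n+c_1}{n+c_2}$, which lose all precision by $n\approx 10^8$ if
  evaluated directly. They are rewritten as `n * log1p((c1-c2)/(n+c2))`,
  whose absolute error at $n = 10^{10}$ is near machine epsilon — orders of
  magnitude below the $10^{-6}$ agreement demanded of the limit checks. For
  this reason the package evaluates everything in ordinary double precision;
  a separate extended-precision mode would add a dependency without changing
  any digit that matters here. The delta functions accept real-valued n
  (the expressions are smooth in n), which the extremum search exploits;
  integer n in the chance example must still be even.
* **Quadrature oracle.** The independent check of every analytic predictive
  integrates likelihood × leave-one-out posterior directly
  (`loo_numeric_oracle()`). Beta integrands are transformed with
  $\theta=\sin^2 u$ so that the endpoint singularities arising for shape
  parameters below 1 (the Jeffreys prior Beta(0.5, 0.5) is a headline case)
  disappear; normal integrands are integrated over ±10 posterior standard
  deviations, beyond which the neglected mass is below $10^{-20}$. Default
  relative tolerance is $10^{-12}$, against an oracle-vs-analytic test bound
  of $10^{-8}$ over a grid of ~200 prior × size × count configurations.
* **Falsified nulls.** $\theta_0=1$ with an observed failure gives a
  legitimate elpd of $-\infty$, carried as a flagged value; `psbf()` and
  `loo_weights()` propagate it to 0/1 weights, and only a comparison of two
  falsified models errors.
* **Log space throughout.** elpd values scale linearly in n and would
  overflow `exp()` by $n\approx1500$; weights use max-subtracted
  exponentiation, and all accumulation is done on log densities.
* **Shape classification.** A trajectory is monotone increasing if all
  successive weight differences exceed $-10^{-12}$ and at least one exceeds
  $+10^{-12}$ (symmetrically for decreasing), else nonmonotone. The
  $10^{-12}$ band separates true nonmonotonicity — e.g. Beta(1, 5) in the
  chance example, or $\sigma_0 = 2.035$ in the normal example, whose interior
  stationary point the package locates by a central-difference derivative
  (step $\max(10^{-4}n, 10^{-3})$) scanned on a log grid and refined by root
  finding — from rounding jitter near the asymptote.
* **Default grids.** Trajectories use a dense head (every n up to 200, or
  every even n up to 400 for the chance example) where the curves bend,
  followed by a 60-point geometric tail to $n = 10^6$, by which point every
  curve sits within 0.02 of its analytic asymptote. These grids reproduce
  the qualitative behavior of the published weight-versus-n figures; the
  original grids were not stated, so the defaults are this package's choice.
* **Acceptance-scale evaluation.** The asymptote checks evaluate the closed
  forms at $n = 10^{10}$, where the residual $O(1/n)$ terms are ~$10^{-10}$
  and the comparison tolerance of $10^{-6}$ is met with headroom.

## Design decisions

* The half-successes layout is deterministic (alternating) so that dataset
  generation is reproducible byte-for-byte without a seed.
* The quadrature oracle is exposed both as `loo_numeric_oracle()` and as
  `elpd_loo(..., method = "quadrature")`, but it exists to *test* the
  analytic path, not to replace it; the analytic route is the default
  everywhere.
* The Bayes factor is deliberately outside the LOO core: it is the foil that
  shows what unbounded accumulation of evidence looks like on the same data.
* The command-line interface is a thin wrapper over exported functions
  (`loo_cli()`); every subcommand is equally reachable from R, and numeric
  output is serialized with 12 significant digits so repeated runs are
  byte-identical.

## Limitations

* Only the two conjugate families are implemented; there is no MCMC or
  importance-sampling LOO, because conjugacy makes them unnecessary here.
* The chance example requires even n by construction; odd integer sizes are
  rejected rather than approximated.
* The asymptotic statements are about idealized law-consistent data;
  stochastic data share the bounds but not the deterministic shapes.
* The package demonstrates a limitation of LOO; it does not implement the
  possible remedies (training-set cost functions, shrinking training sets)
  beyond mentioning them here.
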
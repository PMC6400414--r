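Package: loobound
Title: Bounded Evidence from Bayesian Leave-One-Out Cross-Validation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Closed-form Bayesian leave-one-out cross-validation (LOO) for
    conjugate point-null model comparisons: the Beta-Bernoulli general-law
    and chance tests and the known-variance normal-mean test. Computes
    per-observation leave-one-out predictive densities, elpd_loo,
    pseudo-Bayes factors and LOO model weights, together with their
    analytic large-n limits, an independent quadrature oracle, and
    weight-versus-sample-size trajectories with monotonicity
    classification. Demonstrates that LOO support for a true point null
    is bounded, prior-dependent, and sometimes nonmonotone in the sample
    size.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
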
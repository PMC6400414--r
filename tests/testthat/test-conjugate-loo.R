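# Frozen expected values below were computed from the quadrature oracle
# (direct integration of likelihood times leave-one-out posterior) on
# tiny datasets before the analytic path was trusted.

test_that("Beta-Bernoulli leave-one-out predictives match the quadrature-derived values", {
  u <- beta_prior(1, 1)
  expect_equal(loo_pred_bernoulli(u, bernoulli_data(c(1, 1)), 1), 2 / 3,
               tolerance = 1e-12)
  expect_equal(loo_pred_bernoulli(u, bernoulli_data(c(1, 0)), 1), 1 / 3,
               tolerance = 1e-12)
  expect_equal(loo_pred_bernoulli(u, bernoulli_data(c(1, 0)), 2), 1 / 3,
               tolerance = 1e-12)
  # rule-of-succession form on all-successes data: (a+n-1)/(a+n-1+b)
  for (n in c(3L, 10L, 250L)) {
    d <- make_all_successes(n)
    expect_equal(loo_pred_bernoulli(beta_prior(2, 5), d, 1),
                 (2 + n - 1) / (2 + n - 1 + 5), tolerance = 1e-14)
  }
  expect_error(loo_pred_bernoulli(u, bernoulli_data(c(1, 1)), 3), "index")
})

test_that("normal leave-one-out predictive matches the conjugate posterior-predictive form", {
  pr <- normal_mean_prior(1)
  d <- normal_data(c(1, -1) / sqrt(2))
  # leave out y1 = c: remaining mean -c, posterior N(-c/2, 1/2),
  # predictive N(-c/2, 3/2) evaluated at c
  c0 <- 1 / sqrt(2)
  expect_equal(loo_pred_normal(pr, d, 1),
               dnorm(c0, mean = -c0 / 2, sd = sqrt(3 / 2)),
               tolerance = 1e-14)
  # prior collapsing on the null: predictive tends to the standard normal
  tight <- normal_mean_prior(1e-12)
  expect_equal(loo_pred_normal(tight, d, 1), dnorm(c0), tolerance = 1e-6)
  expect_error(loo_pred_normal(pr, normal_data(0.3), 1), "n >= 2")
})

test_that("point-null LOO estimates equal the summed fixed-parameter log likelihood", {
  # theta = 1 on all successes: perfect prediction, elpd = 0
  expect_identical(elpd_loo(point_null("bernoulli", 1),
                            make_all_successes(12))$elpd, 0)
  # theta = 1/2 on any Bernoulli data: -n log 2
  for (n in c(2L, 8L, 100L)) {
    expect_equal(elpd_loo(point_null("bernoulli", 0.5),
                          make_half_successes(n))$elpd,
                 -n * log(2), tolerance = 1e-12)
  }
  # mu = 0 on exactly standardized data: -(n/2) log(2 pi) - (n-1)/2
  for (n in c(2L, 5L, 60L)) {
    d <- make_standardized_normal(n, seed = n)
    expect_equal(elpd_loo(point_null("normal", 0), d)$elpd,
                 -(n / 2) * log(2 * pi) - (n - 1) / 2, tolerance = 1e-10)
  }
})

test_that("a falsified general law yields -Inf elpd as a flagged value, not an error", {
  res <- elpd_loo(point_null("bernoulli", 1), bernoulli_data(c(1, 1, 0)))
  expect_identical(res$elpd, -Inf)
  expect_true(res$zero_probability)
  expect_identical(res$pointwise_log_pred[3], -Inf)
})

test_that("quadrature oracle agrees with analytic LOO across the Bernoulli grid", {
  for (g in beta_shape_grid()) {
    pr <- beta_prior(g$a, g$b)
    for (n in c(2L, 4L, 8L, 16L)) {
      for (k in 0:n) {
        d <- bern_with_k(n, k)
        a <- elpd_loo(pr, d)
        o <- loo_numeric_oracle(pr, d)
        expect_lt(abs(a$elpd - o$elpd), 1e-8)
      }
    }
  }
})

test_that("quadrature oracle agrees with analytic LOO across the normal grid", {
  for (s0sq in normal_prior_grid()) {
    pr <- normal_mean_prior(s0sq)
    for (n in c(2L, 5L, 10L, 50L)) {
      d <- make_standardized_normal(n, seed = n + 1000L)
      a <- elpd_loo(pr, d)
      o <- loo_numeric_oracle(pr, d)
      expect_lt(abs(a$elpd - o$elpd), 1e-8)
      expect_lt(max(abs(a$pointwise_log_pred - o$pointwise_log_pred)), 1e-8)
    }
  }
})

test_that("elpd is invariant under permutation of the observations", {
  set.seed(42)
  yb <- sample(c(rep(1, 6), rep(0, 4)))
  db <- bernoulli_data(yb)
  dbp <- bernoulli_data(rev(yb))
  expect_equal(elpd_loo(beta_prior(2, 3), db)$elpd,
               elpd_loo(beta_prior(2, 3), dbp)$elpd, tolerance = 1e-12)
  dn <- make_standardized_normal(15, seed = 8)
  dnp <- normal_data(rev(dn$y))
  expect_equal(elpd_loo(normal_mean_prior(2.25), dn)$elpd,
               elpd_loo(normal_mean_prior(2.25), dnp)$elpd, tolerance = 1e-12)
})

test_that("the two Bernoulli predictive cases at a common leave-one-out posterior sum to 1", {
  # datasets sharing y_{-i}: successes-first layout, toggle the last entry
  for (g in beta_shape_grid()) {
    pr <- beta_prior(g$a, g$b)
    for (n in c(3L, 7L)) {
      for (k_rest in 0:(n - 1L)) {
        d1 <- bernoulli_data(c(rep(1, k_rest), rep(0, n - 1L - k_rest), 1))
        d0 <- bernoulli_data(c(rep(1, k_rest), rep(0, n - 1L - k_rest), 0))
        p1 <- loo_pred_bernoulli(pr, d1, n)
        p0 <- loo_pred_bernoulli(pr, d0, n)
        expect_equal(p1 + p0, 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("model/data family mismatches and malformed priors are rejected", {
  expect_error(elpd_loo(beta_prior(1, 1), make_standardized_normal(5, seed = 1)),
               "does not match")
  expect_error(beta_prior(0, 1), "a > 0")
  expect_error(normal_mean_prior(-1), "sigma0_sq > 0")
  expect_error(point_null("bernoulli", 1.2), "\\[0, 1\\]")
})
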
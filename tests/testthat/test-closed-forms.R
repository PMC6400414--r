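test_that("closed-form elpd differences match hand-derived small-n values", {
  u <- beta_prior(1, 1)
  expect_equal(delta_elpd_induction(u, 2), 2 * log(3 / 2), tolerance = 1e-14)
  expect_equal(delta_elpd_chance(u, 2), 2 * log(3 / 2), tolerance = 1e-14)
  expect_equal(delta_elpd_normal(normal_mean_prior(1), 2),
               log(3 / 2) + 1 / 4, tolerance = 1e-14)
  # vague normal prior: 1/sigma0^2 -> 0 gives log 2 + 1/2 at n = 2
  expect_equal(delta_elpd_normal(normal_mean_prior(1e12), 2),
               log(2) + 1 / 2, tolerance = 1e-9)
  # symmetric Beta: the two chance log terms coincide
  expect_equal(delta_elpd_chance(beta_prior(3, 3), 10),
               10 * log((3 + 3 + 9) / (2 * 3 + 8)), tolerance = 1e-12)
})

test_that("H1 closed forms match hand-derived values and the H0 - delta identity", {
  u <- beta_prior(1, 1)
  expect_equal(elpd_h1_closed_form("induction", u, 2), 2 * log(2 / 3),
               tolerance = 1e-14)
  expect_equal(elpd_h1_closed_form("chance", u, 2), 2 * log(1 / 3),
               tolerance = 1e-14)
  expect_equal(elpd_h1_closed_form("normal_mean", normal_mean_prior(1), 2),
               -log(2 * pi) - log(3 / 2) - 3 / 4, tolerance = 1e-14)
  # identity delta = elpd_H0 - elpd_H1 on all three families
  for (g in beta_shape_grid()) {
    pr <- beta_prior(g$a, g$b)
    for (n in c(2, 6, 40, 1000)) {
      expect_equal(delta_elpd_induction(pr, n),
                   elpd_h0_closed_form("induction", n) -
                     elpd_h1_closed_form("induction", pr, n),
                   tolerance = 1e-12)
      expect_equal(delta_elpd_chance(pr, n),
                   elpd_h0_closed_form("chance", n) -
                     elpd_h1_closed_form("chance", pr, n),
                   tolerance = 1e-12)
    }
  }
  for (s0sq in normal_prior_grid()) {
    pr <- normal_mean_prior(s0sq)
    for (n in c(2, 6, 40, 1000)) {
      expect_equal(delta_elpd_normal(pr, n),
                   elpd_h0_closed_form("normal_mean", n) -
                     elpd_h1_closed_form("normal_mean", pr, n),
                   tolerance = 1e-12)
    }
  }
})

test_that("closed forms agree with the generic LOO engine on idealized data", {
  for (g in beta_shape_grid()) {
    pr <- beta_prior(g$a, g$b)
    for (n in c(2L, 4L, 10L, 64L)) {
      eng_ind <- elpd_loo(point_null("bernoulli", 1), make_all_successes(n))$elpd -
        elpd_loo(pr, make_all_successes(n))$elpd
      expect_equal(delta_elpd_induction(pr, n), eng_ind, tolerance = 1e-10)
      eng_cha <- elpd_loo(point_null("bernoulli", 0.5), make_half_successes(n))$elpd -
        elpd_loo(pr, make_half_successes(n))$elpd
      expect_equal(delta_elpd_chance(pr, n), eng_cha, tolerance = 1e-10)
    }
  }
  for (s0sq in normal_prior_grid()) {
    pr <- normal_mean_prior(s0sq)
    for (n in c(2L, 10L, 64L)) {
      d <- make_standardized_normal(n, seed = n)
      eng <- elpd_loo(point_null("normal", 0), d)$elpd - elpd_loo(pr, d)$elpd
      expect_equal(delta_elpd_normal(pr, n), eng, tolerance = 1e-10)
    }
  }
})

test_that("elpd differences converge to their analytic limits, eventually monotonically", {
  for (g in beta_shape_grid()) {
    pr <- beta_prior(g$a, g$b)
    err_ind <- abs(delta_elpd(  "induction", pr, c(1e4, 1e6, 1e8)) - pr$b)
    expect_lt(err_ind[3], 1e-4)
    expect_true(all(diff(err_ind) < 0))
    err_cha <- abs(delta_elpd("chance", pr, c(1e4, 1e6, 1e8)) - 1)
    expect_lt(err_cha[3], 1e-4)
    expect_true(all(diff(err_cha) < 0))
    # prior independence of the chance limit at very large n
    expect_lt(abs(delta_elpd_chance(pr, 1e10) - 1), 1e-6)
  }
  for (s0sq in normal_prior_grid()) {
    pr <- normal_mean_prior(s0sq)
    err <- abs(delta_elpd("normal_mean", pr, c(1e4, 1e6, 1e8)) - 1)
    expect_lt(err[3], 1e-4)
    expect_true(all(diff(err) < 0))
    expect_lt(abs(delta_elpd_normal(pr, 1e10) - 1), 1e-6)
  }
})

test_that("asymptotic limit objects obey their internal identities", {
  for (b in c(0.5, 1, 2, 5)) {
    lim <- loo_limits("induction", beta_prior(1, b))
    expect_equal(lim$delta_elpd_limit, b)
    expect_equal(lim$psbf_limit, exp(b), tolerance = 1e-14)
    expect_equal(lim$w0_limit, exp(b) / (1 + exp(b)), tolerance = 1e-14)
  }
  expect_equal(loo_limits("induction", beta_prior(1, 1))$w0_limit,
               0.731, tolerance = 5e-4)
  expect_equal(loo_limits("induction", beta_prior(1, 5))$w0_limit,
               0.9933, tolerance = 5e-4)
  for (ex in c("chance", "normal_mean")) {
    pr <- if (ex == "chance") beta_prior(0.5, 5) else normal_mean_prior(2.25)
    lim <- loo_limits(ex, pr)
    expect_equal(lim$delta_elpd_limit, 1)
    expect_equal(lim$psbf_limit, exp(1), tolerance = 1e-14)
    expect_equal(lim$w0_limit, plogis(1), tolerance = 1e-14)
  }
})

test_that("maximum-likelihood LOO finds all-successes data uninformative at every n", {
  for (n in c(2, 100, 1e6)) expect_identical(mle_loo_induction(n), 0)
  # independent route: both models predict the held-out success with the
  # MLE theta-hat = (n-1)/(n-1) = 1, so the log predictive gap is zero
  n <- 25
  theta_hat <- (n - 1) / (n - 1)
  expect_identical(0 - n * log(theta_hat), 0)
})

test_that("parity and size rules for the closed forms", {
  expect_error(delta_elpd_chance(beta_prior(1, 1), 7), "even")
  expect_silent(delta_elpd_chance(beta_prior(1, 1), 7.5))  # continuous-n use
  expect_error(delta_elpd_induction(beta_prior(1, 1), 0.5), ">= 1")
  expect_error(delta_elpd_normal(normal_mean_prior(1), 1), ">= 2")
})
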
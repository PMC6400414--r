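#' Closed-form elpd difference, induction example
#'
#' For n all-success Bernoulli observations, \eqn{H_0: \theta = 1}
#' against \eqn{H_1: \theta ~ Beta(a, b)}:
#' \deqn{\Delta elpd = -n \log((a + n - 1)/(a + n - 1 + b)),}
#' evaluated as \code{n * log1p(b / (a + n - 1))} so that no precision is
#' lost at astronomically large n.  The value is strictly positive for
#' all finite n and tends to b as n grows.
#'
#' @param prior a [beta_prior()].
#' @param n sample size; any real n >= 1 is accepted (the expression is
#'   smooth in n, which the trajectory tools exploit).
#' @return \eqn{\Delta elpd = elpd_{H_0} - elpd_{H_1}}.
#' @examples
#' delta_elpd_induction(beta_prior(1, 1), 2)     # 2 log(3/2)
#' delta_elpd_induction(beta_prior(1, 1), 1e10)  # ~ 1
#' @export
delta_elpd_induction <- function(prior, n) {
  stopifnot(inherits(prior, "beta_prior"))
  n <- check_real_n(n, min = 1)
  n * log1p(prior$b / (prior$a + n - 1))
}

#' Closed-form elpd difference, chance example
#'
#' For n Bernoulli observations with exactly n/2 successes,
#' \eqn{H_0: \theta = 1/2} against \eqn{H_1: \theta ~ Beta(a, b)}:
#' \deqn{\Delta elpd = (n/2) \log\frac{a+b+n-1}{2a+n-2}
#'                   + (n/2) \log\frac{a+b+n-1}{2b+n-2},}
#' computed through \code{log1p} for stability.  The limit as n grows is
#' 1, whatever the prior.
#'
#' @param prior a [beta_prior()].
#' @param n sample size.  Integer n must be even (the half-successes
#'   regime pairs each success with a failure); non-integer real n >= 2
#'   is accepted for continuous-in-n analysis.
#' @return \eqn{\Delta elpd = elpd_{H_0} - elpd_{H_1}}.
#' @examples
#' delta_elpd_chance(beta_prior(1, 1), 2)  # 2 log(3/2)
#' @export
delta_elpd_chance <- function(prior, n) {
  stopifnot(inherits(prior, "beta_prior"))
  n <- check_real_n(n, min = 2, even_if_integer = TRUE)
  a <- prior$a; b <- prior$b
  (n / 2) * (log1p((b - a + 1) / (2 * a + n - 2)) +
             log1p((a - b + 1) / (2 * b + n - 2)))
}

#' Closed-form elpd difference, normal-mean example
#'
#' For n normal observations (known unit variance) with sample mean
#' exactly 0 and sample variance exactly 1, \eqn{H_0: \mu = 0} against
#' \eqn{H_1: \mu ~ N(0, \sigma_0^2)}:
#' \deqn{\Delta elpd = (n/2) \log\frac{n + 1/\sigma_0^2}{n - 1 + 1/\sigma_0^2}
#'                   + \frac{n - 1}{2 (n - 1 + 1/\sigma_0^2)}.}
#' The limit as n grows is 1, whatever the prior variance.
#'
#' @param prior a [normal_mean_prior()].
#' @param n sample size; any real n >= 2 is accepted.
#' @return \eqn{\Delta elpd = elpd_{H_0} - elpd_{H_1}}.
#' @examples
#' delta_elpd_normal(normal_mean_prior(1), 2)  # log(3/2) + 1/4
#' @export
delta_elpd_normal <- function(prior, n) {
  stopifnot(inherits(prior, "normal_mean_prior"))
  n <- check_real_n(n, min = 2)
  tau <- 1 / prior$sigma0_sq
  (n / 2) * log1p(1 / (n - 1 + tau)) + (n - 1) / (2 * (n - 1 + tau))
}

#' Closed-form elpd difference by example id
#'
#' Dispatcher over the three idealized regimes.
#'
#' @param example_id \code{"induction"}, \code{"chance"} or
#'   \code{"normal_mean"}.
#' @param prior a [beta_prior()] (induction, chance) or
#'   [normal_mean_prior()] (normal_mean).
#' @param n sample size (vectorized).
#' @return \eqn{\Delta elpd = elpd_{H_0} - elpd_{H_1}} for each n.
#' @export
delta_elpd <- function(example_id = c("induction", "chance", "normal_mean"),
                       prior, n) {
  example_id <- match.arg(example_id)
  f <- switch(example_id,
              induction = delta_elpd_induction,
              chance = delta_elpd_chance,
              normal_mean = delta_elpd_normal)
  vapply(n, function(ni) f(prior, ni), numeric(1))
}

#' Closed-form elpd of the point null in each example
#'
#' The null has no free parameters, so its LOO estimate is the summed
#' fixed-parameter log likelihood: 0 (induction, all successes),
#' \eqn{-n \log 2} (chance) and
#' \eqn{-(n/2)\log(2\pi) - (n-1)/2} (normal mean on exactly
#' standardized data).
#'
#' @inheritParams delta_elpd
#' @param n sample size.
#' @return The null model's elpd_loo.
#' @export
elpd_h0_closed_form <- function(example_id = c("induction", "chance",
                                               "normal_mean"), n) {
  example_id <- match.arg(example_id)
  switch(example_id,
         induction = {check_real_n(n, 1); 0},
         chance = -check_real_n(n, 2, even_if_integer = TRUE) * log(2),
         normal_mean = {n <- check_real_n(n, 2)
                        -(n / 2) * log(2 * pi) - (n - 1) / 2})
}

#' Closed-form elpd of the alternative in each example
#'
#' The alternative's LOO estimate on the idealized data:
#' \eqn{n \log((a+n-1)/(a+n-1+b))} for induction;
#' \eqn{(n/2)\log\frac{a+n/2-1}{a+b+n-1} + (n/2)\log\frac{b+n/2-1}{a+b+n-1}}
#' for chance; and the three-term normal expression for the normal mean.
#' Each equals the corresponding null closed form minus the matching
#' delta, an identity exercised in the test suite.
#'
#' @inheritParams delta_elpd
#' @param n sample size.
#' @return The alternative model's elpd_loo.
#' @export
elpd_h1_closed_form <- function(example_id = c("induction", "chance",
                                               "normal_mean"), prior, n) {
  example_id <- match.arg(example_id)
  switch(example_id,
    induction = {
      stopifnot(inherits(prior, "beta_prior"))
      n <- check_real_n(n, 1)
      n * log((prior$a + n - 1) / (prior$a + n - 1 + prior$b))
    },
    chance = {
      stopifnot(inherits(prior, "beta_prior"))
      n <- check_real_n(n, 2, even_if_integer = TRUE)
      a <- prior$a; b <- prior$b
      (n / 2) * (log((a + n / 2 - 1) / (a + b + n - 1)) +
                 log((b + n / 2 - 1) / (a + b + n - 1)))
    },
    normal_mean = {
      stopifnot(inherits(prior, "normal_mean_prior"))
      n <- check_real_n(n, 2)
      tau <- 1 / prior$sigma0_sq
      -(n / 2) * log(2 * pi) - (n / 2) * log((n + tau) / (n - 1 + tau)) -
        (n - 1) * (n + tau) / (2 * (n - 1 + tau))
    })
}

#' Analytic large-n limits of the LOO comparison
#'
#' The asymptotic elpd difference, pseudo-Bayes factor and null-model
#' weight: \eqn{\Delta_\infty = b} for induction (prior-dependent even in
#' the limit), and \eqn{\Delta_\infty = 1} for both the chance and
#' normal-mean examples regardless of the prior; then
#' \eqn{PSBF_\infty = e^{\Delta_\infty}} and
#' \eqn{w_{0,\infty} = PSBF_\infty / (1 + PSBF_\infty)}.
#'
#' @inheritParams delta_elpd
#' @return An object of class \code{"loo_limits"}: list with
#'   \code{delta_elpd_limit}, \code{psbf_limit}, \code{w0_limit}.
#' @examples
#' loo_limits("induction", beta_prior(1, 1))$w0_limit  # e/(1+e) ~ 0.731
#' loo_limits("chance", beta_prior(1, 5))$psbf_limit   # e ~ 2.718
#' @export
loo_limits <- function(example_id = c("induction", "chance", "normal_mean"),
                       prior) {
  example_id <- match.arg(example_id)
  if (example_id == "normal_mean") stopifnot(inherits(prior, "normal_mean_prior"))
  else stopifnot(inherits(prior, "beta_prior"))
  d <- if (example_id == "induction") prior$b else 1
  structure(list(example_id = example_id,
                 delta_elpd_limit = d,
                 psbf_limit = exp(d),
                 w0_limit = stats::plogis(d)),
            class = "loo_limits")
}

#' @export
print.loo_limits <- function(x, ...) {
  cat(sprintf("Asymptotic LOO comparison (%s example):\n", x$example_id))
  cat(sprintf("  Delta elpd -> %g   PSBF01 -> %g   w0 -> %g\n",
              x$delta_elpd_limit, x$psbf_limit, x$w0_limit))
  invisible(x)
}

#' Maximum-likelihood LOO for the induction example
#'
#' With all-successes data, every training fold of size n - 1 gives the
#' MLE \eqn{\hat\theta = 1} under the alternative, so both models predict
#' the held-out success with probability one and the elpd difference is
#' exactly zero for every n: under maximum-likelihood LOO the data are
#' completely uninformative about the general law.
#'
#' @param n sample size, n >= 2 (a training fold must be nonempty).
#' @return 0, for any valid n.
#' @export
mle_loo_induction <- function(n) {
  n <- check_real_n(n, min = 2)
  # MLE from n-1 successes is (n-1)/(n-1) = 1: identical predictions
  0
}

# n may be real-valued (the closed forms are smooth in n); integer n in
# the chance example must be even.
check_real_n <- function(n, min, even_if_integer = FALSE) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n))
    stop("n must be a finite numeric scalar")
  if (n < min) stop("n must be >= ", min, " (got ", n, ")")
  if (even_if_integer && n == round(n) && as.numeric(n) %% 2 != 0)
    stop("the chance example requires an even n (got ", n,
         "): observations come as success/failure pairs")
  as.numeric(n)
}
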
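#' Pseudo-Bayes factor from two elpd values
#'
#' \eqn{PSBF_{01} = \exp(elpd_0 - elpd_1)}: the ratio of the two models'
#' products of leave-one-out predictive densities.  An elpd of
#' \code{-Inf} (a falsified model) propagates to 0 or \code{Inf}; two
#' falsified models cannot be compared.
#'
#' @param elpd0,elpd1 elpd_loo values (finite or \code{-Inf}).
#' @return \eqn{\exp(elpd_0 - elpd_1)}, a nonnegative number.
#' @examples
#' psbf(0, -1)  # e
#' @export
psbf <- function(elpd0, elpd1) {
  stopifnot(is.numeric(elpd0), length(elpd0) == 1L, !is.na(elpd0),
            is.numeric(elpd1), length(elpd1) == 1L, !is.na(elpd1))
  if (elpd0 == -Inf && elpd1 == -Inf)
    stop("both models have elpd = -Inf: the pseudo-Bayes factor is undefined")
  if (elpd0 == -Inf) return(0)
  if (elpd1 == -Inf) return(Inf)
  exp(elpd0 - elpd1)
}

#' LOO model weights
#'
#' Normalized exponentiated elpd values across M candidate models,
#' \deqn{w_m = \exp(elpd_m) / \sum_j \exp(elpd_j),} computed with
#' max-subtraction so that elpd values of any magnitude (they scale
#' linearly in n) neither overflow nor underflow.  \code{-Inf} entries
#' (falsified models) receive weight 0.
#'
#' @param elpds numeric vector of M >= 2 elpd values, at least one
#'   finite.
#' @return A weight vector summing to 1.
#' @examples
#' loo_weights(c(0, -1))      # c(0.731, 0.269)
#' loo_weights(c(0, -1000))   # no underflow: c(1, ~0)
#' @export
loo_weights <- function(elpds) {
  if (length(elpds) == 0L) stop("loo_weights() needs a nonempty elpd vector")
  stopifnot(is.numeric(elpds), !anyNA(elpds))
  if (length(elpds) < 2L) stop("model weights need at least two models")
  m <- max(elpds)
  if (m == -Inf) stop("all models have elpd = -Inf: weights are undefined")
  e <- exp(elpds - m)
  e / sum(e)
}

#' Marginal-likelihood Bayes factor for a conjugate point-null comparison
#'
#' \eqn{BF_{01} = p(y | H_0) / p(y | H_1)}, the ratio of marginal
#' likelihoods, supplied as a contrast to the LOO quantities: on data
#' perfectly consistent with the null the Bayes factor grows without
#' bound in n while the pseudo-Bayes factor stays below a fixed bound.
#' For the Beta-Bernoulli family the alternative's marginal is the Beta
#' function ratio \eqn{B(a+k, b+n-k)/B(a, b)}; for the normal mean with
#' known unit variance it is
#' \eqn{BF_{01} = \sqrt{1 + n\sigma_0^2}\,
#'      \exp\{-(n\bar y)^2 \sigma_0^2 / (2(1 + n\sigma_0^2))\}}.
#'
#' @param null a [point_null()].
#' @param prior a [beta_prior()] or [normal_mean_prior()] of the same
#'   family.
#' @param data the dataset.
#' @param log if \code{TRUE}, return \eqn{\log BF_{01}}.
#' @return The Bayes factor \eqn{BF_{01}} (0 when the null assigns the
#'   data zero probability).
#' @examples
#' bayes_factor(point_null("bernoulli", 1), beta_prior(1, 1),
#'              make_all_successes(10))  # n + 1 = 11
#' @export
bayes_factor <- function(null, prior, data, log = FALSE) {
  stopifnot(inherits(null, "point_null"))
  check_model_data(null, data)
  check_model_data(prior, data)
  if (null$family == "bernoulli") {
    stopifnot(inherits(prior, "beta_prior"))
    log_m0 <- sum(stats::dbinom(data$y, 1L, null$value, log = TRUE))
    log_m1 <- lbeta(prior$a + data$k, prior$b + data$n - data$k) -
      lbeta(prior$a, prior$b)
    lbf <- log_m0 - log_m1
  } else {
    stopifnot(inherits(prior, "normal_mean_prior"))
    s0 <- prior$sigma0_sq
    n <- data$n
    # alternative's marginal relative to the mu = 0 likelihood (the prior
    # is centred at 0); the null may sit elsewhere
    log_m1_over_l0 <- -0.5 * log1p(n * s0) +
      (n * data$ybar)^2 * s0 / (2 * (1 + n * s0))
    log_l_ratio <- sum(stats::dnorm(data$y, null$value, 1, log = TRUE)) -
      sum(stats::dnorm(data$y, 0, 1, log = TRUE))
    lbf <- log_l_ratio - log_m1_over_l0
  }
  if (log) lbf else exp(lbf)
}

#' Compare a point null with a conjugate alternative by LOO
#'
#' The package's central comparison: computes each model's LOO estimate
#' on the data, their difference, the pseudo-Bayes factor
#' \eqn{PSBF_{01} = \exp(\Delta elpd)}, the two-model weights, and
#' (optionally) the marginal-likelihood Bayes factor for contrast.
#'
#' @param null a [point_null()].
#' @param alternative a [beta_prior()] or [normal_mean_prior()].
#' @param data a dataset of the matching family.
#' @param method passed to [elpd_loo()] (\code{"analytic"} or
#'   \code{"quadrature"}).
#' @param bf whether to also compute the Bayes factor.
#' @return An object of class \code{"loo_comparison"}: list with
#'   \code{elpd0}, \code{elpd1}, \code{delta_elpd}, \code{psbf01},
#'   \code{w0}, \code{w1}, \code{bf01} (or \code{NULL}), plus the inputs
#'   and per-model \code{"loo_result"}s under \code{fits}.
#' @examples
#' loo_compare(point_null("bernoulli", 0.5), beta_prior(1, 1),
#'             make_half_successes(10))
#' @export
loo_compare <- function(null, alternative, data,
                        method = c("analytic", "quadrature"), bf = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(null, "point_null"))
  fit0 <- elpd_loo(null, data, method = method)
  fit1 <- elpd_loo(alternative, data, method = method)
  d <- fit0$elpd - fit1$elpd
  ps <- psbf(fit0$elpd, fit1$elpd)
  w <- loo_weights(c(fit0$elpd, fit1$elpd))
  structure(list(elpd0 = fit0$elpd, elpd1 = fit1$elpd,
                 delta_elpd = d, psbf01 = ps, w0 = w[1], w1 = w[2],
                 bf01 = if (bf) bayes_factor(null, alternative, data) else NULL,
                 null = null, alternative = alternative,
                 n = data$n, method = method,
                 fits = list(h0 = fit0, h1 = fit1)),
            class = "loo_comparison")
}

#' @export
print.loo_comparison <- function(x, digits = 6, ...) {
  cat(sprintf("LOO comparison on n = %d observations (%s predictives)\n",
              x$n, x$method))
  cat("  "); print(x$null)
  cat("  "); print(x$alternative)
  cat(sprintf("  elpd_loo:  H0 = %s,  H1 = %s\n",
              format(x$elpd0, digits = digits),
              format(x$elpd1, digits = digits)))
  cat(sprintf("  Delta elpd = %s   PSBF01 = %s   w0 = %s   w1 = %s\n",
              format(x$delta_elpd, digits = digits),
              format(x$psbf01, digits = digits),
              format(x$w0, digits = digits),
              format(x$w1, digits = digits)))
  if (!is.null(x$bf01))
    cat(sprintf("  (marginal-likelihood Bayes factor BF01 = %s)\n",
                format(x$bf01, digits = digits)))
  invisible(x)
}

#' @export
summary.loo_comparison <- function(object, ...) {
  out <- c(n = object$n, elpd0 = object$elpd0, elpd1 = object$elpd1,
           delta_elpd = object$delta_elpd, psbf01 = object$psbf01,
           w0 = object$w0, w1 = object$w1)
  if (!is.null(object$bf01)) out <- c(out, bf01 = object$bf01)
  class(out) <- "summary.loo_comparison"
  out
}

#' @export
print.summary.loo_comparison <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}
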
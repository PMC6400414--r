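#' Beta prior for a Bernoulli probability
#'
#' Defines the alternative model \eqn{H_1: \theta ~ Beta(a, b)} for the
#' Bernoulli comparisons.
#'
#' @param a,b positive shape parameters.
#' @return An object of class \code{c("beta_prior", "loo_model")}.
#' @examples
#' beta_prior(1, 1)     # Laplace / uniform
#' beta_prior(0.5, 0.5) # Jeffreys
#' @export
beta_prior <- function(a, b) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(b), length(b) == 1L, is.finite(b))
  if (a <= 0 || b <= 0)
    stop("beta_prior() requires a > 0 and b > 0")
  structure(list(a = as.numeric(a), b = as.numeric(b)),
            class = c("beta_prior", "loo_model"))
}

#' Zero-centred normal prior for a normal mean
#'
#' Defines the alternative model \eqn{H_1: \mu ~ N(0, \sigma_0^2)} for the
#' normal-mean comparison (observation variance known and equal to 1).
#'
#' @param sigma0_sq positive prior variance \eqn{\sigma_0^2}.
#' @return An object of class \code{c("normal_mean_prior", "loo_model")}.
#' @examples
#' normal_mean_prior(1)
#' normal_mean_prior(2.035^2)
#' @export
normal_mean_prior <- function(sigma0_sq) {
  stopifnot(is.numeric(sigma0_sq), length(sigma0_sq) == 1L, is.finite(sigma0_sq))
  if (sigma0_sq <= 0)
    stop("normal_mean_prior() requires sigma0_sq > 0")
  structure(list(sigma0_sq = as.numeric(sigma0_sq)),
            class = c("normal_mean_prior", "loo_model"))
}

#' Point-null model
#'
#' A model that fixes the parameter at a single value: \eqn{\theta = value}
#' for the Bernoulli family or \eqn{\mu = value} for the normal family
#' (known unit observation variance).  The three canonical nulls are
#' \eqn{\theta = 1} (general law), \eqn{\theta = 1/2} (chance) and
#' \eqn{\mu = 0}, but any value in the parameter domain is accepted.
#'
#' @param family \code{"bernoulli"} or \code{"normal"}.
#' @param value the fixed parameter value; must lie in \code{[0, 1]} for
#'   the Bernoulli family, any finite real for the normal family.
#' @return An object of class \code{c("point_null", "loo_model")}.
#' @examples
#' point_null("bernoulli", 1)
#' point_null("normal", 0)
#' @export
point_null <- function(family = c("bernoulli", "normal"), value) {
  family <- match.arg(family)
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  if (family == "bernoulli" && (value < 0 || value > 1))
    stop("Bernoulli point null requires value in [0, 1]")
  structure(list(family = family, value = as.numeric(value)),
            class = c("point_null", "loo_model"))
}

# Likelihood family a model belongs to.
model_family <- function(model) {
  if (inherits(model, "point_null")) return(model$family)
  if (inherits(model, "beta_prior")) return("bernoulli")
  if (inherits(model, "normal_mean_prior")) return("normal")
  stop("not a loo_model object")
}

#' @export
print.beta_prior <- function(x, ...) {
  cat(sprintf("H1: theta ~ Beta(%g, %g)  [Bernoulli family]\n", x$a, x$b))
  invisible(x)
}

#' @export
print.normal_mean_prior <- function(x, ...) {
  cat(sprintf("H1: mu ~ N(0, %g)  [normal family, obs. variance 1]\n",
              x$sigma0_sq))
  invisible(x)
}

#' @export
print.point_null <- function(x, ...) {
  par <- if (x$family == "bernoulli") "theta" else "mu"
  cat(sprintf("H0: %s = %g  [%s family]\n", par, x$value, x$family))
  invisible(x)
}

#' Simulate data from a point-null model
#'
#' Draws i.i.d. observations from the likelihood with the parameter fixed
#' at the null value: Bernoulli(\code{value}) or N(\code{value}, 1).
#'
#' @param object a [point_null()] model.
#' @param nsim number of observations to draw.
#' @param seed mandatory integer seed; the caller's RNG state is left
#'   untouched.
#' @param ... unused.
#' @return A [bernoulli_data()] or [normal_data()] object of size
#'   \code{nsim}.
#' @export
simulate.point_null <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) stop("simulate() for loo models requires an explicit seed")
  sample_from_model(object$family, object$value, n = nsim, seed = seed)
}
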
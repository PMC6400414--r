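#' Bernoulli dataset
#'
#' Container for a vector of binary outcomes together with its size n and
#' success count k.
#'
#' @param y vector of outcomes, each 0 or 1.
#' @return An object of class \code{c("bernoulli_data", "loo_data")} with
#'   fields \code{y}, \code{n} and \code{k}.
#' @examples
#' bernoulli_data(c(1, 0, 1, 1))
#' @export
bernoulli_data <- function(y) {
  y <- as.numeric(y)
  if (length(y) < 1L) stop("a Bernoulli dataset needs n >= 1 observations")
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("Bernoulli outcomes must all be 0 or 1")
  structure(list(y = as.integer(y), n = length(y), k = as.integer(sum(y))),
            class = c("bernoulli_data", "loo_data"))
}

#' Normal dataset
#'
#' Container for a vector of real-valued observations together with its
#' size, sample mean and sample variance (n - 1 denominator).
#'
#' @param y numeric vector of observations.
#' @return An object of class \code{c("normal_data", "loo_data")} with
#'   fields \code{y}, \code{n}, \code{ybar} and \code{s2} (\code{s2} is
#'   \code{NA} when n = 1).
#' @examples
#' normal_data(c(-0.5, 0.5))
#' @export
normal_data <- function(y) {
  y <- as.numeric(y)
  if (length(y) < 1L) stop("a normal dataset needs n >= 1 observations")
  if (anyNA(y) || !all(is.finite(y))) stop("normal outcomes must be finite")
  structure(list(y = y, n = length(y), ybar = mean(y),
                 s2 = if (length(y) >= 2L) stats::var(y) else NA_real_),
            class = c("normal_data", "loo_data"))
}

#' @export
print.bernoulli_data <- function(x, ...) {
  cat(sprintf("Bernoulli dataset: n = %d, k = %d successes\n", x$n, x$k))
  invisible(x)
}

#' @export
print.normal_data <- function(x, ...) {
  cat(sprintf("Normal dataset: n = %d, mean = %.6g, s^2 = %.6g\n",
              x$n, x$ybar, x$s2))
  invisible(x)
}

#' All-successes Bernoulli data
#'
#' The idealized induction regime: n observations, every one a
#' confirmatory instance (success), so the data are perfectly consistent
#' with the general law \eqn{\theta = 1}.
#'
#' @param n number of observations, n >= 1.
#' @return A [bernoulli_data()] with \code{k = n}.
#' @examples
#' make_all_successes(5)
#' @export
make_all_successes <- function(n) {
  n <- check_count(n, min = 1, what = "make_all_successes()")
  bernoulli_data(rep(1L, n))
}

#' Half-successes Bernoulli data
#'
#' The idealized chance regime: an even number of observations with
#' exactly n/2 successes, so the data are perfectly consistent with
#' \eqn{\theta = 1/2}.  The outcomes are laid out deterministically as
#' alternating 1, 0, 1, 0, ...; the ordering is immaterial because every
#' leave-one-out predictive depends on the data only through the total
#' success count and the held-out value.
#'
#' @param n even number of observations, n >= 2.
#' @return A [bernoulli_data()] with \code{k = n/2}.
#' @examples
#' make_half_successes(10)
#' @export
make_half_successes <- function(n) {
  n <- check_count(n, min = 2, what = "make_half_successes()")
  if (n %% 2L != 0L)
    stop("make_half_successes() requires an even n (got ", n,
         "): the data come as success/failure pairs")
  bernoulli_data(rep(c(1L, 0L), n / 2L))
}

#' Exactly standardized normal data
#'
#' The idealized normal-mean regime: n observations whose sample mean is
#' exactly 0 and whose sample variance (n - 1 denominator) is exactly 1,
#' so the data are perfectly consistent with \eqn{\mu = 0} under unit
#' observation variance.  Raw values are drawn from a standard normal
#' with the given seed and then affinely standardized; degenerate draws
#' (zero spread) are redrawn.
#'
#' @param n number of observations, n >= 2 (the sample variance is
#'   undefined below that).
#' @param seed mandatory integer seed; the caller's RNG state is left
#'   untouched.
#' @return A [normal_data()] with \code{ybar == 0} and \code{s2 == 1} to
#'   floating-point tolerance.
#' @examples
#' d <- make_standardized_normal(20, seed = 1)
#' c(d$ybar, d$s2)
#' @export
make_standardized_normal <- function(n, seed) {
  n <- check_count(n, min = 2, what = "make_standardized_normal()")
  y <- with_seed(seed, {
    x <- stats::rnorm(n)
    while (stats::sd(x) == 0) x <- stats::rnorm(n)
    x
  })
  normal_data((y - mean(y)) / stats::sd(y))
}

#' Sample noisy data from a likelihood family
#'
#' Draws n i.i.d. observations from Bernoulli(\code{value}) or
#' N(\code{value}, 1).  Unlike the \code{make_*} generators, these data
#' are only consistent with the point null in expectation, not exactly.
#'
#' @param family \code{"bernoulli"} or \code{"normal"}.
#' @param value the true parameter (\eqn{\theta \in [0,1]} or \eqn{\mu}
#'   real).
#' @param n number of observations.
#' @param seed mandatory integer seed; the caller's RNG state is left
#'   untouched.
#' @return A [bernoulli_data()] or [normal_data()].
#' @examples
#' sample_from_model("bernoulli", 0.5, n = 10, seed = 42)
#' @export
sample_from_model <- function(family = c("bernoulli", "normal"), value, n, seed) {
  family <- match.arg(family)
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  n <- check_count(n, min = 1, what = "sample_from_model()")
  if (family == "bernoulli") {
    if (value < 0 || value > 1)
      stop("Bernoulli parameter must lie in [0, 1]")
    bernoulli_data(with_seed(seed, stats::rbinom(n, 1L, value)))
  } else {
    normal_data(with_seed(seed, stats::rnorm(n, mean = value, sd = 1)))
  }
}

#' Read outcomes from a one-value-per-line text file
#'
#' Blank lines and lines starting with \code{#} are ignored, as is
#' trailing \code{#}-comment text on a value line.
#'
#' @param file path to a text file with one numeric value per line.
#' @param family optional; if \code{"bernoulli"} or \code{"normal"}, the
#'   values are wrapped in the corresponding dataset container, otherwise
#'   the bare numeric vector is returned.
#' @return A numeric vector, or a [bernoulli_data()] / [normal_data()]
#'   when \code{family} is given.
#' @export
read_outcomes <- function(file, family = NULL) {
  lines <- readLines(file)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  y <- suppressWarnings(as.numeric(lines))
  if (anyNA(y)) stop("non-numeric value in ", file)
  if (is.null(family)) return(y)
  switch(match.arg(family, c("bernoulli", "normal")),
         bernoulli = bernoulli_data(y),
         normal = normal_data(y))
}

#' Write outcomes to a one-value-per-line text file
#'
#' @param data a dataset object or bare numeric vector.
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_outcomes <- function(data, file) {
  y <- if (inherits(data, "loo_data")) data$y else as.numeric(data)
  writeLines(format(y, digits = 17, scientific = FALSE, trim = TRUE), file)
  invisible(file)
}

# Run expr with a private RNG stream; the caller's .Random.seed survives.
with_seed <- function(seed, expr) {
  if (missing(seed) || is.null(seed))
    stop("an explicit integer seed is required; no hidden RNG state is used")
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Positive-integer size check shared by the generators.
check_count <- function(n, min, what) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n != round(n))
    stop(what, " requires an integer sample size")
  if (n < min) stop(what, " requires n >= ", min, " (got ", n, ")")
  as.integer(n)
}
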
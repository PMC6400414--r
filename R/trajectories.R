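#' Default sample-size grid for an example
#'
#' Dense coverage of the small-n range where the curves bend (matching
#' the visual range of the weight-versus-n figures), then a geometric
#' tail out to n = 1e6 to probe the asymptote.  The chance grid contains
#' only even n.
#'
#' @param example_id \code{"induction"}, \code{"chance"} or
#'   \code{"normal_mean"}.
#' @param n_max upper end of the geometric tail.
#' @return An increasing integer-valued numeric vector.
#' @export
default_n_grid <- function(example_id = c("induction", "chance", "normal_mean"),
                           n_max = 1e6) {
  example_id <- match.arg(example_id)
  tail_from <- function(lo) {
    g <- round(exp(seq(log(lo), log(n_max), length.out = 60)))
    g
  }
  grid <- switch(example_id,
    induction = c(1:200, tail_from(201)),
    chance = {
      g <- c(seq(2, 400, by = 2), tail_from(402))
      g + g %% 2  # round the geometric tail up to even
    },
    normal_mean = c(2:200, tail_from(201)))
  sort(unique(grid))
}

#' LOO weight trajectory for the null model
#'
#' Evaluates \eqn{w_0(n) = PSBF_{01}(n) / (1 + PSBF_{01}(n))
#' = logistic(\Delta elpd(n))} over a grid of sample sizes for one of
#' the three idealized regimes, attaches the analytic asymptote, and
#' classifies the shape of the approach (monotone increasing, monotone
#' decreasing, or nonmonotone).
#'
#' @inheritParams delta_elpd
#' @param n_grid increasing vector of valid sample sizes; defaults to
#'   [default_n_grid()].
#' @param tolerance slack on successive weight differences when
#'   classifying the shape; differences within \code{tolerance} of zero
#'   are treated as ties (default \code{1e-12}, enough to separate real
#'   nonmonotonicity from rounding jitter).
#' @return An object of class \code{"loo_trajectory"}: list with
#'   \code{example_id}, \code{prior}, \code{n_grid}, \code{w0_values},
#'   \code{asymptote}, \code{shape}.
#' @examples
#' tr <- weight_trajectory("induction", beta_prior(1, 1))
#' tr$shape       # monotone_increasing
#' tr$asymptote   # e/(1+e)
#' @export
weight_trajectory <- function(example_id = c("induction", "chance",
                                             "normal_mean"),
                              prior, n_grid = NULL, tolerance = 1e-12) {
  example_id <- match.arg(example_id)
  if (is.null(n_grid)) n_grid <- default_n_grid(example_id)
  if (length(n_grid) < 3L) stop("n_grid needs at least 3 sample sizes")
  if (is.unsorted(n_grid, strictly = TRUE))
    stop("n_grid must be strictly increasing")
  min_n <- if (example_id == "induction") 1 else 2
  if (any(n_grid < min_n))
    stop("the ", example_id, " example requires n >= ", min_n)
  if (example_id == "chance" && any(n_grid %% 2 != 0))
    stop("the chance example requires an even-n grid",
         " (observations come as success/failure pairs)")
  d <- delta_elpd(example_id, prior, n_grid)
  w0 <- stats::plogis(d)
  structure(list(example_id = example_id, prior = prior,
                 n_grid = n_grid, w0_values = w0,
                 asymptote = loo_limits(example_id, prior)$w0_limit,
                 shape = classify_shape(w0, tolerance)),
            class = "loo_trajectory")
}

#' Classify the shape of a weight sequence
#'
#' Monotone increasing if every successive difference is above
#' \code{-tolerance} and at least one exceeds \code{tolerance};
#' symmetrically for decreasing; otherwise nonmonotone.
#'
#' @param w0_values numeric vector of at least 3 weights.
#' @param tolerance nonnegative slack on the differences.
#' @return \code{"monotone_increasing"}, \code{"monotone_decreasing"} or
#'   \code{"nonmonotone"}.
#' @examples
#' classify_shape(c(0.1, 0.3, 0.2))  # "nonmonotone"
#' @export
classify_shape <- function(w0_values, tolerance = 1e-12) {
  stopifnot(is.numeric(w0_values), tolerance >= 0)
  if (length(w0_values) < 3L)
    stop("shape classification needs at least 3 values")
  d <- diff(w0_values)
  if (all(d >= -tolerance) && any(d > tolerance)) "monotone_increasing"
  else if (all(d <= tolerance) && any(d < -tolerance)) "monotone_decreasing"
  else "nonmonotone"
}

#' Locate an interior extremum of the elpd difference in n
#'
#' Treats \eqn{\Delta elpd(n)} as a smooth function of real-valued n and
#' searches \code{n_range} for a stationary point: the numerical
#' derivative (central differences with step
#' \code{max(1e-4 n, 1e-3)}) is scanned on a log-spaced grid for a sign
#' change, which is then refined by root finding.  A prior that yields a
#' nonmonotone weight trajectory (e.g. \eqn{\sigma_0 = 2.035} in the
#' normal-mean example) produces an interior extremum; a monotone one
#' returns \code{NULL}.
#'
#' @inheritParams delta_elpd
#' @param n_range length-2 numeric range to search.
#' @param grid_points number of scan points.
#' @return The location n* of the stationary point, or \code{NULL} if
#'   the derivative never changes sign on the range.
#' @examples
#' find_interior_extremum("normal_mean", normal_mean_prior(2.035^2))
#' @export
find_interior_extremum <- function(example_id = c("induction", "chance",
                                                  "normal_mean"),
                                   prior, n_range = c(2, 1e6),
                                   grid_points = 400) {
  example_id <- match.arg(example_id)
  stopifnot(length(n_range) == 2L, n_range[1] < n_range[2])
  min_n <- if (example_id == "induction") 1 else 2
  if (n_range[1] < min_n)
    stop("n_range must start at or above ", min_n, " for this example")
  dfun <- function(n) {
    h <- pmax(1e-4 * n, 1e-3)
    (delta_elpd(example_id, prior, n + h) -
     delta_elpd(example_id, prior, n - h)) / (2 * h)
  }
  grid <- exp(seq(log(n_range[1] + 1e-3), log(n_range[2]),
                  length.out = grid_points))
  dv <- dfun(grid)
  sgn <- sign(dv)
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(flip) == 0L) return(NULL)
  j <- flip[1]
  stats::uniroot(dfun, lower = grid[j], upper = grid[j + 1],
                 tol = 1e-8)$root
}

#' Curve data behind the three weight-versus-n figures
#'
#' Emits the full trajectory data for the published prior grids:
#' figure 1 (induction; Beta(1,5), Beta(5,5), Beta(2,2), Beta(1,1),
#' Beta(0.5,0.5)), figure 2 (chance; the same five Beta priors) and
#' figure 3 (normal mean; N(0, 3^2), N(0, 1.5^2), N(0, 1),
#' N(0, 0.5^2)), each case carrying its analytic asymptote for the
#' dotted reference line.
#'
#' @param figure_id 1, 2 or 3.
#' @param n_max upper end of each curve's grid.
#' @return A data.frame with columns \code{case}, \code{prior_label},
#'   \code{n}, \code{w0}, \code{asymptote}, \code{shape}.
#' @export
figure_data <- function(figure_id, n_max = 1e6) {
  if (!figure_id %in% c(1, 2, 3)) stop("unknown figure id: ", figure_id)
  if (figure_id %in% c(1, 2)) {
    example <- if (figure_id == 1) "induction" else "chance"
    priors <- list(a = beta_prior(1, 5), b = beta_prior(5, 5),
                   c = beta_prior(2, 2), d = beta_prior(1, 1),
                   e = beta_prior(0.5, 0.5))
    labels <- vapply(priors, function(p) sprintf("Beta(%g, %g)", p$a, p$b),
                     character(1))
  } else {
    example <- "normal_mean"
    priors <- list(a = normal_mean_prior(9), b = normal_mean_prior(2.25),
                   c = normal_mean_prior(1), d = normal_mean_prior(0.25))
    labels <- vapply(priors, function(p)
      sprintf("N(0, %g)", p$sigma0_sq), character(1))
  }
  grid <- default_n_grid(example, n_max = n_max)
  out <- lapply(names(priors), function(case) {
    tr <- weight_trajectory(example, priors[[case]], n_grid = grid)
    data.frame(case = case, prior_label = labels[[case]],
               n = tr$n_grid, w0 = tr$w0_values,
               asymptote = tr$asymptote, shape = tr$shape,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.loo_trajectory <- function(x, ...) {
  cat(sprintf("LOO weight trajectory (%s example), %d sample sizes in [%g, %g]\n",
              x$example_id, length(x$n_grid), min(x$n_grid), max(x$n_grid)))
  cat("  prior: "); print(x$prior)
  cat(sprintf("  shape: %s;  asymptote w0 = %.6f;  final w0 = %.6f\n",
              x$shape, x$asymptote, x$w0_values[length(x$w0_values)]))
  invisible(x)
}

#' Plot a LOO weight trajectory
#'
#' Weight for the null model against sample size (log axis), with the
#' analytic asymptote as a dotted horizontal reference line.
#'
#' @param x a \code{"loo_trajectory"}.
#' @param ... further arguments to [graphics::plot()].
#' @return \code{x}, invisibly.
#' @export
plot.loo_trajectory <- function(x, ...) {
  graphics::plot(x$n_grid, x$w0_values, type = "l", log = "x",
                 xlab = "sample size n", ylab = expression(w[0]),
                 ylim = range(c(x$w0_values, x$asymptote, 0.5, 1)), ...)
  graphics::abline(h = x$asymptote, lty = 3)
  invisible(x)
}
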
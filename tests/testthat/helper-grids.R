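# Shared parameter grids for property-style tests.

beta_shape_grid <- function() {
  g <- expand.grid(a = c(0.5, 1, 2, 5), b = c(0.5, 1, 2, 5))
  split(g, seq_len(nrow(g)))
}

normal_prior_grid <- function() c(0.25, 1, 2.25, 9)

# Bernoulli dataset with a given success count, successes first.
bern_with_k <- function(n, k) {
  bernoulli_data(c(rep(1L, k), rep(0L, n - k)))
}
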
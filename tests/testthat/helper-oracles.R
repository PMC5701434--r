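# Independent oracles used across the suite. These deliberately avoid the
# code paths they validate: quantiles by bisection instead of the closed
# form, marginal prevalence by adaptive quadrature instead of the normal-tail
# identity, Poisson-binomial by exhaustive enumeration instead of the DP
# convolution.

# Upper-tail exponential quantile by bisection on the survival function.
bisect_upper_quantile <- function(p, rate, lo = 0, hi = 100, tol = 1e-12) {
  f <- function(t) exp(-rate * t) - p
  stopifnot(f(lo) > 0, f(hi) < 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# P(X > T), X ~ Exp(rate), T ~ N(mean, sd^2), by quadrature over the
# threshold density: integral of dnorm((t-mean)/sd)/sd * min(1, exp(-rate*max(t,0))).
quadrature_marginal_prevalence <- function(mean, sd, rate) {
  f <- function(t) stats::dnorm(t, mean, sd) * exp(-rate * pmax(t, 0))
  stats::integrate(f, mean - 12 * sd, mean + 12 * sd,
                   rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# Poisson-binomial pmf by enumerating all 2^Q outcomes (tiny Q only).
enumerate_poisson_binomial <- function(probs) {
  q <- length(probs)
  pmf <- numeric(q + 1)
  for (mask in 0:(2^q - 1)) {
    bits <- as.integer(intToBits(mask))[1:q]
    pr <- prod(ifelse(bits == 1, probs, 1 - probs))
    k <- sum(bits)
    pmf[k + 1] <- pmf[k + 1] + pr
  }
  pmf
}

# Small instruments reused across files.
toy_instrument <- function(n_questions = 10L)
  instrument(paste0("q", seq_len(n_questions)), rep(1L, n_questions))
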
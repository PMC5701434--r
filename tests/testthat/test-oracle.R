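test_that("conditional endorsement probabilities follow the threshold family", {
  spec <- normal_thresholds(c(1, 2.5), sd = 1)
  expect_equal(item_prob_given_latent(1, spec, 1), 0.5)     # at the mean
  expect_equal(item_prob_given_latent(2.5, spec, 2), 0.5)
  u <- uniform_thresholds(0, 5)
  expect_equal(item_prob_given_latent(2.5, u), 0.5)          # midpoint
  expect_equal(item_prob_given_latent(7, u), 1)              # clamp above b
  expect_equal(item_prob_given_latent(0, u), 0)
  # sd = 0 is a step at the mean
  step <- normal_thresholds(2, sd = 0)
  expect_equal(item_prob_given_latent(c(1.9, 2, 2.1), step, 1), c(0, 0, 1))
  expect_error(item_prob_given_latent(-1, u), "nonnegative")
})

test_that("Poisson-binomial DP matches enumeration and the binomial reduction", {
  expect_equal(poisson_binomial_pmf(c(0.5, 0.5)), c(0.25, 0.5, 0.25))
  # frozen from exhaustive enumeration of the 4 outcomes
  expect_equal(poisson_binomial_pmf(c(0.2, 0.7)), c(0.24, 0.62, 0.14))
  # random probability vectors vs the enumeration oracle
  set.seed(301)
  for (q in c(3, 6, 10)) {
    probs <- runif(q)
    expect_equal(poisson_binomial_pmf(probs),
                 enumerate_poisson_binomial(probs), tolerance = 1e-12)
  }
  # equal probabilities collapse to the binomial
  expect_equal(poisson_binomial_pmf(rep(0.3, 12)), dbinom(0:12, 12, 0.3),
               tolerance = 1e-12)
  expect_error(poisson_binomial_pmf(c(0.5, 1.2)), "probabilities")
})

test_that("the mixture pmf reproduces closed-form single-question values", {
  one <- instrument("x", 1)
  # uniform(0,5), rate 1: P(total = 1) = (1/5) int_0^5 x e^-x dx + e^-5
  pmf <- total_pmf(one, uniform_thresholds(0, 5), latent_model(1))
  expect_equal(round(pmf$probabilities[2], 5), 0.19865)
  expect_equal(pmf$probabilities[2], 0.2 - 0.2 * exp(-5), tolerance = 1e-8)
  # calibration identity at sd = 0
  for (p in c(0.0549, 0.3)) for (rate in c(1, 2)) {
    spec <- normal_thresholds(exp_upper_quantile(p, rate), sd = 0)
    expect_equal(total_pmf(one, spec, latent_model(rate))$probabilities[2], p,
                 tolerance = 1e-10)
  }
  # P(total = 1) equals the closed-form marginal prevalence (normal family)
  for (sd in c(0.5, 2)) {
    spec <- normal_thresholds(2.9, sd = sd)
    expect_equal(total_pmf(one, spec, latent_model(1))$probabilities[2],
                 marginal_item_prevalence(2.9, sd, 1), tolerance = 1e-6)
  }
})

test_that("mixture pmfs normalize and are exchangeable in question order", {
  toy <- toy_instrument(8)
  pt <- generate_prevalence_table(toy, seed = 31)
  spec <- calibrate_thresholds(pt, latent_model(1), sd = 2)
  pmf <- total_pmf(toy, spec, latent_model(1), tol = 1e-8)
  expect_true(all(pmf$probabilities >= 0))
  expect_lt(abs(sum(pmf$probabilities) - 1), 10 * pmf$tol)
  # permuting the questions leaves the total-score law unchanged
  perm <- normal_thresholds(rev(spec$means), sd = spec$sd)
  pmf_perm <- total_pmf(toy, perm, latent_model(1), tol = 1e-8)
  expect_equal(pmf$probabilities, pmf_perm$probabilities, tolerance = 1e-8)
})

test_that("uniform thresholds give full-range log-linearity in the exact pmf", {
  pmf <- total_pmf(cisr_instrument(), uniform_thresholds(0, 5), latent_model(1))
  probs <- pmf$probabilities
  fit <- fit_log_linear(pmf, "full_range", min_count = 1e-8)
  expect_gte(fit$r_squared, 0.98)
  # the exact distribution has its mode at 0 (no left tail)
  expect_equal(which.max(probs) - 1L, 0L)
  # the ceiling bin is a censoring atom: all latent mass above the uniform
  # upper bound endorses every question
  expect_equal(probs[58], exp(-5), tolerance = 0.1)
  expect_gt(probs[58], exp(fit$intercept + fit$slope * 57))
})

test_that("pmfs export as score,probability CSV", {
  pmf <- total_pmf(toy_instrument(4),
                   uniform_thresholds(0, 5), latent_model(1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_total_pmf(pmf, path)
  back <- read.csv(path)
  expect_equal(back$score, 0:4)
  expect_equal(back$probability, pmf$probabilities, tolerance = 1e-10)
})
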
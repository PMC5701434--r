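test_that("latent draws have exponential support, mean and sd", {
  set.seed(101)
  n <- 1e5
  x1 <- draw_latent(n, latent_model(1))
  expect_true(all(x1 >= 0))
  expect_lt(abs(mean(x1) - 1), 3 / sqrt(n))
  x2 <- draw_latent(n, latent_model(2))
  # sd of Exp(rate) is 1/rate
  expect_lt(abs(sd(x2) - 0.5), 3 * 0.5 / sqrt(n))
  expect_error(draw_latent(0, latent_model(1)), "positive")
})

test_that("threshold draws follow the requested family", {
  set.seed(102)
  # degenerate normal: every column constant at its mean
  spec0 <- normal_thresholds(c(1, 2, 3), sd = 0)
  m0 <- draw_thresholds(4, spec0)
  expect_equal(m0, matrix(rep(c(1, 2, 3), each = 4), 4, 3))
  # uniform bounds respected, applied to every question
  mu <- draw_thresholds(1000, uniform_thresholds(0, 5), n_questions = 8)
  expect_equal(dim(mu), c(1000L, 8L))
  expect_true(all(mu >= 0 & mu <= 5))
  # LLN on one question's mean
  n <- 1e5
  m1 <- draw_thresholds(n, normal_thresholds(2.9, sd = 2))
  expect_lt(abs(mean(m1) - 2.9), 3 * 2 / sqrt(n))
  # uniform spec needs an explicit question count
  expect_error(draw_thresholds(10, uniform_thresholds(0, 5)), "question count")
})

test_that("binary scoring is a strict comparison", {
  expect_equal(score_binary(2.0, matrix(1.5)), matrix(1L))
  expect_equal(score_binary(1.5, matrix(1.5)), matrix(0L))  # tie scores 0
  thr <- matrix(Inf, 5, 3)
  sc <- score_binary(rexp(5), thr)
  expect_true(all(sc == 0L))
  expect_equal(rowSums(sc), rep(0, 5))
  expect_error(score_binary(1:3, matrix(0, 2, 2)), "one row per latent")
})

test_that("simulated conditions are reproducible and bounded", {
  cfg <- sim_config(1, "normal", sd = 2, n = 2000, seed = 42)
  r1 <- simulate_condition(cfg)
  r2 <- simulate_condition(cfg)
  expect_identical(r1$totals, r2$totals)
  expect_true(all(r1$totals >= 0 & r1$totals <= 57))
  expect_equal(r1$totals, as.integer(rowSums(r1$scores)))
  # a different seed gives a different realization
  r3 <- simulate_condition(sim_config(1, "normal", sd = 2, n = 2000, seed = 43))
  expect_false(identical(r1$totals, r3$totals))
  # simulate_condition leaves the caller's RNG stream untouched
  set.seed(7); before <- runif(1)
  set.seed(7); invisible(simulate_condition(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("raising a respondent's latent value never lowers any score", {
  set.seed(103)
  thr <- draw_thresholds(200, uniform_thresholds(-1, 6), n_questions = 12)
  x <- rexp(200)
  sc <- score_binary(x, thr)
  sc_up <- score_binary(x + rexp(200), thr)
  expect_true(all(sc_up >= sc))
  expect_true(all(rowSums(sc_up) >= rowSums(sc)))
})

test_that("empirical prevalence converges to the closed-form marginal", {
  # familywise bound across 57 questions x 8 conditions: Bonferroni-adjusted
  # z for an overall 3-sigma-equivalent level (alpha = 0.0027)
  inst <- cisr_instrument()
  pt <- fixture_prevalence_table(inst)
  n <- 1e5
  conds <- expand.grid(sd = c(0, 1, 2, 4), rate = c(1, 2))
  z <- qnorm(1 - 0.0027 / 2 / (57 * nrow(conds)))
  for (i in seq_len(nrow(conds))) {
    sd <- conds$sd[i]; rate <- conds$rate[i]
    res <- simulate_condition(
      sim_config(rate, "normal", sd = sd, n = n, seed = 500 + i), inst, pt)
    mu <- exp_upper_quantile(pt$prevalence, rate)
    truth <- marginal_item_prevalence(mu, sd, rate)
    se <- sqrt(truth * (1 - truth) / n)
    expect_true(all(abs(res$empirical_prevalence - truth) <= z * se),
                info = sprintf("sd=%g rate=%g", sd, rate))
  }
})

test_that("empirical total-score pmf matches the analytic oracle (TV <= 0.01)", {
  toy <- toy_instrument(10)
  pt <- generate_prevalence_table(toy, seed = 21)
  n <- 1e5
  for (rate in c(1, 2)) for (sd in c(1, 2)) {
    res <- simulate_condition(
      sim_config(rate, "normal", sd = sd, n = n, seed = 600 + 10 * rate + sd),
      toy, pt)
    spec <- calibrate_thresholds(pt, latent_model(rate), sd)
    oracle <- total_pmf(toy, spec, latent_model(rate))
    expect_lte(tv_distance(empirical_pmf(res), oracle$probabilities), 0.01)
  }
})

test_that("sim results export totals, histogram and config echo", {
  cfg <- sim_config(1, "uniform", a = 0, b = 5, n = 500, seed = 3)
  res <- simulate_condition(cfg)
  dir <- withr::local_tempdir()
  write_sim_result(res,
                   totals_path = file.path(dir, "totals.csv"),
                   hist_path = file.path(dir, "hist.csv"),
                   config_path = file.path(dir, "config.json"))
  totals <- read.csv(file.path(dir, "totals.csv"))
  expect_equal(totals$total, res$totals)
  h <- read.csv(file.path(dir, "hist.csv"))
  expect_equal(sum(h$count), 500)
  echo <- jsonlite::fromJSON(file.path(dir, "config.json"))
  expect_equal(echo$seed, 3)
  expect_equal(echo$family, "uniform")
})
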
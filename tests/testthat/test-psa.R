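test_that("fixed distributions pass parameter values through unchanged", {
  dists <- list(param_dist("a", "fixed", mean = 0.4),
                param_dist("b", "fixed", mean = 120))
  set.seed(1)
  s <- sample_parameters(dists)
  expect_identical(s, list(a = 0.4, b = 120))
})

test_that("uniform sampling has the right moments", {
  d <- param_dist("p", "uniform", ci = c(0.1, 0.3))
  set.seed(5)
  x <- replicate(50000, sample_parameters(list(d))$p)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 0.2), 3 * se)
  expect_true(all(x >= 0.1 & x <= 0.3))
})

test_that("beta and gamma fits hit the stated 95% CI quantiles", {
  b <- param_dist("p", "beta", mean = 0.2, ci = c(0.1, 0.3))
  expect_lt(abs(qbeta(0.025, b$fit$shape1, b$fit$shape2) - 0.1), 1e-6)
  expect_lt(abs(qbeta(0.975, b$fit$shape1, b$fit$shape2) - 0.3), 1e-6)
  g <- param_dist("c", "gamma", mean = 100, ci = c(60, 150))
  expect_lt(abs(qgamma(0.025, g$fit$shape, g$fit$rate) - 60), 1e-4)
  expect_lt(abs(qgamma(0.975, g$fit$shape, g$fit$rate) - 150), 1e-4)
  # sampled percentiles recover the CI
  set.seed(2)
  x <- rbeta(20000, b$fit$shape1, b$fit$shape2)
  expect_lt(abs(quantile(x, 0.025) - 0.1), 0.01)
  expect_lt(abs(quantile(x, 0.975) - 0.3), 0.01)
})

test_that("a mean outside its CI is rejected by name", {
  expect_error(param_dist("p_bad", "beta", mean = 0.5, ci = c(0.1, 0.3)),
               "p_bad")
  expect_error(param_dist("c_bad", "gamma", mean = 50, ci = c(60, 150)),
               "c_bad")
})

test_that("percentile intervals interpolate order statistics", {
  expect_identical(percentile_ci(rep(7, 10)), c(7, 7))
  expect_equal(percentile_ci(0:100), c(2.5, 97.5))
  set.seed(3)
  x <- rnorm(200)
  expect_identical(percentile_ci(x), percentile_ci(sample(x)))
  expect_error(percentile_ci(5), "at least 2")
})

test_that("the PSA loop is reproducible and consistent with single runs", {
  toy <- build_fee_threshold_toy()
  r1 <- run_psa(toy, list(), n_psa = 5, n_individuals = 50, seed = 77)
  r2 <- run_psa(toy, list(), n_psa = 5, n_individuals = 50, seed = 77)
  expect_identical(r1$draws, r2$draws)
  expect_identical(r1$summary, r2$summary)

  # n_psa = 1 with no uncertainty equals one simulate_cohort pair
  r <- run_psa(toy, list(), n_psa = 1, n_individuals = 40, seed = 10)
  b <- toy$build(toy$params)
  set.seed(10)
  invisible(sample.int(.Machine$integer.max - 1L, 1L))
  sim_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  ai <- simulate_cohort(b$spec, b$rewards, b$arms$ai, toy$params, n = 40,
                        seed = sim_seed, discount_rate = 0,
                        validate = FALSE)
  expect_identical(r$draws$cost_ai, ai$mean_cost)
  expect_identical(r$draws$effect_ai, ai$mean_effect)
})

test_that("replicate spread shrinks as cohorts grow", {
  pars <- generate_default_params("dentistry", seed = 1)$params
  model <- use_case_model("dentistry", pars)
  widths <- vapply(c(60, 1500), function(n) {
    r <- run_psa(model, list(), n_psa = 25, n_individuals = n, seed = 4)
    ci <- percentile_ci(r$draws$effect_ai)
    ci[2] - ci[1]
  }, numeric(1))
  expect_lt(widths[2], widths[1])
})

test_that("sweeping an inert parameter yields constant rows", {
  toy <- build_fee_threshold_toy()
  toy$params$inert <- 1
  sw <- one_way_sweep(toy, "inert", c(0, 1, 2), n = 30, seed = 3)
  expect_identical(length(unique(sw$delta_cost)), 1L)
  expect_identical(length(unique(sw$delta_effect)), 1L)
  expect_null(find_threshold(sw))
})

test_that("fee sweeps raise AI costs monotonically, never effects", {
  toy <- build_fee_threshold_toy()
  sw <- one_way_sweep(toy, "fee", seq(0, 32, 4), n = 30, seed = 3)
  expect_true(all(diff(sw$cost_ai) > 0))
  expect_identical(length(unique(sw$effect_ai)), 1L)
  expect_identical(length(unique(sw$delta_effect)), 1L)
})

test_that("the toy fee break-even point is savings over test count", {
  toy <- build_fee_threshold_toy(treatment_savings = 64, n_tests = 4)
  sw <- one_way_sweep(toy, "fee", seq(0, 32, 8), n = 20, seed = 1)
  thr <- find_threshold(sw, tol = 0.01)
  expect_lt(abs(thr - 16), 0.01)
  # and the threshold is invariant to the grid used
  sw2 <- one_way_sweep(toy, "fee", seq(10, 20, 5), n = 20, seed = 1)
  thr2 <- find_threshold(sw2, tol = 0.01)
  expect_lt(abs(thr2 - thr), 0.02)
})

test_that("unknown sweep parameters are named in the error", {
  toy <- build_fee_threshold_toy()
  expect_error(one_way_sweep(toy, "no_such_knob", 0:1, n = 10, seed = 1),
               "no_such_knob")
})
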
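test_that("identical seeds reproduce cohorts bit-identically", {
  m <- two_state_model(0.3, cost_rate = 100)
  a <- simulate_cohort(m$spec, m$rewards, NULL, n = 500, seed = 11,
                       discount_rate = 0.03)
  b <- simulate_cohort(m$spec, m$rewards, NULL, n = 500, seed = 11,
                       discount_rate = 0.03)
  expect_identical(a, b)
  c2 <- simulate_cohort(m$spec, m$rewards, NULL, n = 500, seed = 12,
                        discount_rate = 0.03)
  expect_false(identical(a$cost, c2$cost))
})

test_that("entry into a zero-reward absorbing state ends immediately", {
  spec <- markov_model(
    c("Alive", "Death"), absorbing = "Death", entry_age = 70,
    entry_state_distribution = c(Death = 1), max_age = 100,
    transition_fn = function(state, age, params, treated) {
      if (state == "Death") c(Death = 1) else c(Alive = 0.5, Death = 0.5)
    })
  rewards <- reward_spec(state_cost = c(Alive = 50),
                         state_effect = c(Alive = 1))
  tr <- simulate_individual(spec, rewards, seed = 1)
  expect_identical(nrow(tr$records), 1L)
  expect_identical(tr$records$state, "Death")
  expect_identical(tr$total_cost, 0)
  expect_identical(tr$total_effect, 0)
})

test_that("a certain one-cycle life accrues exactly one effect unit", {
  m <- two_state_model(1)
  res <- simulate_cohort(m$spec, m$rewards, NULL, n = 50, seed = 4,
                         discount_rate = 0)
  expect_true(all(res$effect == 1))
})

test_that("geometric survival means 1/p years of life", {
  p <- 0.2
  m <- two_state_model(p)
  res <- simulate_cohort(m$spec, m$rewards, NULL, n = 20000, seed = 21,
                         discount_rate = 0)
  se <- sd(res$effect) / sqrt(res$n)
  expect_lt(abs(res$mean_effect - 1 / p), 3 * se)
})

test_that("per-individual effects mean matches the reported mean", {
  m <- two_state_model(0.25, cost_rate = 10)
  res <- simulate_cohort(m$spec, m$rewards, NULL, n = 300, seed = 9,
                         discount_rate = 0.03)
  expect_identical(res$mean_cost, mean(res$cost))
  expect_identical(res$mean_effect, mean(res$effect))
})

test_that("raising the discount rate never raises discounted totals", {
  for (seed in 1:3) {
    m <- two_state_model(0.15, cost_rate = 80)
    out <- lapply(c(0, 0.03, 0.08), function(r)
      simulate_cohort(m$spec, m$rewards, NULL, n = 400, seed = seed,
                      discount_rate = r))
    costs <- vapply(out, `[[`, numeric(1), "mean_cost")
    effects <- vapply(out, `[[`, numeric(1), "mean_effect")
    expect_true(all(diff(costs) <= 0))
    expect_true(all(diff(effects) <= 0))
    # and per-individual: discounted never exceeds undiscounted
    expect_true(all(out[[2]]$cost <= out[[1]]$cost + 1e-12))
  }
})

test_that("trajectories never leave an absorbing state once entered", {
  # a reward-bearing absorbing state stays on the record until the horizon
  spec <- markov_model(
    c("Well", "Impaired"), absorbing = "Impaired", entry_age = 0,
    entry_state_distribution = c(Well = 1), max_age = 15,
    transition_fn = function(state, age, params, treated) {
      if (state == "Impaired") c(Impaired = 1)
      else c(Well = 0.7, Impaired = 0.3)
    })
  rewards <- reward_spec(state_effect = c(Well = 1, Impaired = 0.5))
  res <- simulate_cohort(spec, rewards, NULL, n = 40, seed = 6,
                         discount_rate = 0, record_trajectories = TRUE)
  tr <- res$trajectories
  expect_true(any(tr$state == "Impaired"))
  for (id in unique(tr$individual)) {
    states <- tr$state[tr$individual == id]
    hit <- which(states == "Impaired")
    if (length(hit) > 0)
      expect_true(all(states[seq(min(hit), length(states))] == "Impaired"))
  }
  # absorbed individuals are carried to the horizon, not dropped
  expect_identical(as.integer(table(tr$individual)), rep(15L, 40))
})

test_that("common random numbers make identical arms coincide exactly", {
  for (uc in c("dermatology", "dentistry", "ophthalmology")) {
    pars <- identical_arm_params(uc, seed = 3)
    b <- switch(uc,
                dermatology = build_melanoma_model(pars),
                dentistry = build_caries_model(pars),
                ophthalmology = build_retinopathy_model(pars))
    ai <- simulate_cohort(b$spec, b$rewards, b$arms$ai, pars, n = 300,
                          seed = 17, discount_rate = 0.03,
                          validate = FALSE)
    std <- simulate_cohort(b$spec, b$rewards, b$arms$standard, pars,
                           n = 300, seed = 17, discount_rate = 0.03,
                           validate = FALSE)
    expect_identical(ai$cost, std$cost)
    expect_identical(ai$effect, std$effect)
  }
})

test_that("the per-use fee changes costs only, never effects", {
  pars <- generate_default_params("dentistry", seed = 1)$params
  lo <- build_caries_model(pars)
  pars_hi <- pars; pars_hi$fee <- pars$fee + 10
  hi <- build_caries_model(pars_hi)
  a <- simulate_cohort(lo$spec, lo$rewards, lo$arms$ai, pars, n = 400,
                       seed = 8, discount_rate = 0.03, validate = FALSE)
  b <- simulate_cohort(hi$spec, hi$rewards, hi$arms$ai, pars_hi, n = 400,
                       seed = 8, discount_rate = 0.03, validate = FALSE)
  expect_identical(a$effect, b$effect)
  expect_true(all(b$cost >= a$cost))
  expect_gt(b$mean_cost, a$mean_cost)
})
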
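test_that("test schedules are deterministic and entry-aligned", {
  expect_identical(schedule_tests(2, 0:4), rep(2L, 5))
  expect_identical(schedule_tests(0.5, 0:3), c(1L, 0L, 1L, 0L))
  expect_identical(sum(schedule_tests(1, 0:9)), 10L)
  expect_identical(sum(schedule_tests(0.5, 0:9)), 5L)
  expect_error(schedule_tests(0, 1))
})

test_that("a perfect test always matches disease status", {
  test <- diagnostic_test(c(Sick = 1), specificity = 1)
  set.seed(1)
  for (i in 1:20) {
    expect_identical(classify("Sick", test, c("Well", "Sick")), "positive")
    expect_identical(classify("Well", test, c("Well", "Sick")), "negative")
  }
})

test_that("positive rates follow sensitivity and total probability", {
  test <- diagnostic_test(c(Sick = 0.85), specificity = 0.9)
  set.seed(42)
  n <- 20000
  pos_sick <- sum(replicate(n, classify("Sick", test, c("Well", "Sick")))
                  == "positive") / n
  expect_lt(abs(pos_sick - 0.85), 3 * sqrt(0.85 * 0.15 / n))
  # prevalence 0.1: overall positive rate 0.1*0.85 + 0.9*(1-0.9) = 0.175
  set.seed(43)
  states <- sample(c("Sick", "Well"), n, replace = TRUE,
                   prob = c(0.1, 0.9))
  pos <- vapply(states, function(s)
    classify(s, test, c("Well", "Sick")) == "positive", logical(1))
  expect_lt(abs(mean(pos) - 0.175), 3 * sqrt(0.175 * 0.825 / n))
})

test_that("states without an accuracy entry are rejected", {
  test <- diagnostic_test(c(Sick = 0.8),
                          specificity = c(Well = 0.9))  # no default
  expect_error(classify("Limbo", test, c("Well", "Sick", "Limbo")),
               "Limbo")
})

test_that("decisions resolve to actions, fees and transition modifiers", {
  states <- c("Well", "Sick")
  strat <- screening_strategy(
    diagnostic_test(c(Sick = 0.8), specificity = 0.9, fee = 8),
    schedule = 2,
    decisions = decision_map(states,
                             positive = c(Well = "refer",
                                          Sick = "treat-invasive"),
                             negative = c(Well = "none", Sick = "monitor")))
  d <- apply_decision("negative", "Sick", strat)
  expect_identical(d$action, "monitor")
  expect_identical(d$fee, 8)
  expect_false(d$treated)
  d <- apply_decision("positive", "Sick", strat)
  expect_identical(d$action, "treat-invasive")
  expect_true(d$treated)
  d <- apply_decision("positive", "Well", strat)
  expect_identical(d$action, "refer")
  expect_false(d$treated)
  expect_error(apply_decision("positive", "Limbo", strat), "Limbo")
  expect_error(decision_map(states, positive = c(Well = "amputate")),
               "unknown actions")
})

test_that("fees accrue as fee x schedule per cycle, pre-discounting", {
  # one cycle of life, 2 tests/year at fee 8 -> exactly 16 accrued
  spec <- markov_model(
    c("Alive", "Dead"), absorbing = "Dead", entry_age = 0,
    entry_state_distribution = c(Alive = 1), max_age = 1,
    transition_fn = function(state, age, params, treated) {
      if (state == "Dead") c(Dead = 1) else c(Dead = 1)
    })
  rewards <- reward_spec(state_effect = c(Alive = 1))
  strat <- screening_strategy(
    diagnostic_test(c(Alive = 0), specificity = 1, fee = 8),
    schedule = 2, decisions = decision_map(c("Alive", "Dead")))
  res <- simulate_cohort(spec, rewards, strat, n = 10, seed = 2,
                         discount_rate = 0)
  expect_true(all(res$cost == 16))
})
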
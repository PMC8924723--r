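builders <- list(dermatology = build_melanoma_model,
                 dentistry = build_caries_model,
                 ophthalmology = build_retinopathy_model)

test_that("every default model configuration validates cleanly", {
  for (uc in names(builders)) {
    pars <- generate_default_params(uc, seed = 1)$params
    b <- builders[[uc]](pars)
    expect_identical(validate_model(b$spec, pars), character(0))
    expect_s3_class(b$arms$ai, "screening_strategy")
    expect_s3_class(b$arms$standard, "screening_strategy")
  }
})

test_that("missing parameters are reported by name", {
  pars <- generate_default_params("dermatology", seed = 1)$params
  pars$p_incidence <- NULL
  expect_error(build_melanoma_model(pars), "p_incidence")
  pars <- generate_default_params("dentistry", seed = 1)$params
  pars$treatment_path <- NULL
  expect_error(build_caries_model(pars), "treatment_path")
  pars <- generate_default_params("ophthalmology", seed = 1)$params
  pars$u_blind <- 1.4
  expect_error(build_retinopathy_model(pars), "utilities")
})

test_that("zero melanoma incidence leaves only screening costs", {
  pars <- generate_default_params("dermatology", seed = 1)$params
  pars$p_incidence <- 0
  pars$spec_ai <- 1        # no false positives, so no biopsy work-ups
  pars$u_healthy <- 1
  b <- build_melanoma_model(pars)
  an <- solve_cohort_analytic(b$spec, b$rewards, b$arms$ai, pars,
                              discount_rate = 0, validate = FALSE)
  # costs: the per-use fee once a year while alive; effect: life expectancy
  lt_model <- life_table_model(pars$life_table, entry_age = pars$entry_age,
                               max_age = pars$max_age)
  le <- solve_cohort_analytic(lt_model$spec, lt_model$rewards, NULL,
                              discount_rate = 0)
  expect_equal(an$cost, pars$fee * le$effect, tolerance = 1e-9)
  expect_equal(an$effect, le$effect, tolerance = 1e-9)
})

test_that("identical arms yield zero incremental quantities everywhere", {
  for (uc in names(builders)) {
    pars <- identical_arm_params(uc, seed = 2)
    b <- builders[[uc]](pars)
    ai <- simulate_cohort(b$spec, b$rewards, b$arms$ai, pars, n = 200,
                          seed = 5, discount_rate = 0.03, validate = FALSE)
    std <- simulate_cohort(b$spec, b$rewards, b$arms$standard, pars,
                           n = 200, seed = 5, discount_rate = 0.03,
                           validate = FALSE)
    ic <- icer(ai$mean_cost - std$mean_cost,
               ai$mean_effect - std$mean_effect)
    expect_identical(ic$flag, "undefined")
    expect_identical(ai$mean_cost - std$mean_cost, 0)
  }
})

test_that("a tooth accrues exactly 0 or 1 retention-year per cycle", {
  pars <- generate_default_params("dentistry", seed = 3)$params
  b <- build_caries_model(pars)
  res <- simulate_cohort(b$spec, b$rewards, b$arms$ai, pars, n = 25,
                         seed = 7, discount_rate = 0.03,
                         record_trajectories = TRUE, validate = FALSE)
  expect_true(all(res$trajectories$effect %in% c(0, 1)))
})

test_that("zero progression keeps the tooth to the horizon", {
  pars <- generate_default_params("dentistry", seed = 1)$params
  pars$p_initiation <- 0
  pars$prev_initial <- 0
  pars$prev_advanced <- 0
  b <- build_caries_model(pars)
  r <- 0.03
  horizon <- pars$max_age - pars$entry_age
  an <- solve_cohort_analytic(b$spec, b$rewards, NULL, pars,
                              discount_rate = r, validate = FALSE)
  expect_equal(an$effect, sum(1 / (1 + r)^(0:(horizon - 1))),
               tolerance = 1e-9)
})

test_that("invasive management restores an overtreated sound tooth", {
  pars <- generate_default_params("dentistry", seed = 1)$params
  pars$treatment_path <- "invasive"
  pars$spec_ai <- 0       # every sound tooth tests positive
  pars$p_initiation <- 0
  pars$prev_initial <- 0
  pars$prev_advanced <- 0
  b <- build_caries_model(pars)
  tr <- simulate_individual(b$spec, b$rewards, b$arms$ai, pars, seed = 2,
                            discount_rate = 0, validate = FALSE)
  expect_identical(tr$records$state[1], "Sound")
  expect_identical(tr$records$state[2], "Restored")
  expect_gte(tr$records$cost[1], pars$c_restoration)
})

test_that("higher specificity never loses retention under invasive care", {
  pars <- generate_default_params("dentistry", seed = 1)$params
  pars$treatment_path <- "invasive"
  pars$fee <- 0
  pars$sens_std <- pars$sens_ai
  pars$spec_ai <- 0.95
  pars$spec_std <- 0.70
  b <- build_caries_model(pars)
  hi <- simulate_cohort(b$spec, b$rewards, b$arms$ai, pars, n = 2000,
                        seed = 9, discount_rate = 0.03, validate = FALSE)
  lo <- simulate_cohort(b$spec, b$rewards, b$arms$standard, pars,
                        n = 2000, seed = 9, discount_rate = 0.03,
                        validate = FALSE)
  expect_gte(hi$mean_effect, lo$mean_effect)
})

test_that("retinopathy without progression yields utility-weighted survival", {
  pars <- generate_default_params("ophthalmology", seed = 1)$params
  pars$p_onset <- 0
  pars$prev_npdr <- 0
  pars$prev_pdr <- 0
  pars$u_nodr <- 1
  b <- build_retinopathy_model(pars)
  an <- solve_cohort_analytic(b$spec, b$rewards, NULL, pars,
                              discount_rate = 0.03, validate = FALSE)
  # matches plain diabetic survival from the same life table
  lt <- pmin(pars$life_table * pars$mort_mult_diabetes, 1)
  m <- life_table_model(lt, entry_age = pars$entry_age,
                        max_age = pars$max_age)
  le <- solve_cohort_analytic(m$spec, m$rewards, NULL,
                              discount_rate = 0.03)
  expect_equal(an$effect, le$effect, tolerance = 1e-9)
})
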
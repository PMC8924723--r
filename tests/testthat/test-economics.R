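test_that("ICERs divide increments and flag degenerate quadrants", {
  expect_equal(icer(100, 2)$ratio, 50)
  expect_identical(icer(10, 0)$flag, "undefined")
  expect_true(is.na(icer(10, 0)$ratio))
  expect_identical(icer(-5, 2)$flag, "dominant")
  expect_identical(icer(5, -2)$flag, "dominated")
  expect_identical(icer(5, 2)$flag, "none")
  # arithmetic on rounded tabulated means: (320.40-342.24)/(62.4-60.9)
  ic <- icer(320.40 - 342.24, 62.4 - 60.9)
  expect_equal(ic$ratio, -14.56)
  expect_identical(ic$flag, "dominant")
})

test_that("net benefit is WTP x delta-effect minus delta-cost, exactly", {
  expect_identical(net_benefit(0, 123.4, 25), -25)
  expect_identical(net_benefit(1000, 0.5, 100), 400)
  expect_identical(net_benefit(50000, 0, -10), 10)
  # affine, strictly increasing in WTP when the effect gain is positive
  w <- seq(0, 1e5, 1e4)
  nb <- net_benefit(w, 0.2, 50)
  expect_true(all(diff(nb) > 0))
  expect_equal(diff(nb), rep(0.2 * 1e4, length(w) - 1))
})

test_that("acceptability is the per-draw positive-net-benefit fraction", {
  # uniform cost saving, no effect difference: certain at every WTP
  d <- ce_draws(cost_ai = rep(90, 10), effect_ai = rep(5, 10),
                cost_std = rep(100, 10), effect_std = rep(5, 10))
  curve <- ceac(d, c(0, 1000, 50000))
  expect_identical(curve$p_cost_effective, rep(1, 3))
  # exact ties count one half
  d0 <- ce_draws(1, 1, 1, 1)
  expect_identical(ceac(d0, 500)$p_cost_effective, 0.5)
  # symmetric draws: half positive, half negative
  ds <- ce_draws(cost_ai = c(90, 110), effect_ai = c(1, 1),
                 cost_std = c(100, 100), effect_std = c(1, 1))
  expect_identical(ceac(ds, 0)$p_cost_effective, 0.5)
  expect_error(ceac(ce_draws(1, 1, 1, 1)[0, ], 100), "replicate")
})

test_that("acceptability equals brute-force counting on random draws", {
  set.seed(99)
  n <- 500
  d <- ce_draws(cost_ai = rnorm(n, 320, 30),
                effect_ai = rnorm(n, 62, 2),
                cost_std = rnorm(n, 342, 30),
                effect_std = rnorm(n, 61, 2))
  wtp <- seq(0, 5000, 500)
  expect_identical(ceac(d, wtp)$p_cost_effective, ceac_oracle(d, wtp))
})

test_that("PPP conversion divides by the rate and is linear", {
  r <- ppp_rates()
  expect_equal(ppp_convert(0, r[["EUR"]]), 0)
  expect_equal(present_money(ppp_convert(320.40, r[["EUR"]])), 429.49)
  expect_equal(present_money(ppp_convert(1321, r[["BRL"]]), 0), 559)
  set.seed(1)
  a <- runif(20, 0, 1e4); b <- runif(20, 0, 1e4)
  expect_equal(ppp_convert(a + b, 2.362),
               ppp_convert(a, 2.362) + ppp_convert(b, 2.362),
               tolerance = 1e-9)
  expect_error(ppp_convert(10, 0))
  expect_error(ppp_convert(10, -1))
})

test_that("presentation rounding is half away from zero", {
  expect_identical(present_money(0.125), 0.13)
  expect_identical(present_money(-0.125), -0.13)
  expect_identical(present_money(2.5, 0), 3)    # not banker's rounding
  expect_identical(present_money(-2.5, 0), -3)
  expect_identical(present_money(559.2718, 0), 559)
})

test_that("the WHO ceiling is three times GDP per capita", {
  expect_identical(who_threshold(1), 3)
  expect_identical(who_threshold(14563), 43689)
  expect_error(who_threshold(-5))
})

test_that("dominance means positive net benefit at every WTP", {
  for (case in list(c(-30, 0.5), c(-1, 2), c(20, 0.5), c(-10, -0.5))) {
    ic <- icer(case[1], case[2])
    nb_all_pos <- all(net_benefit(seq(0, 1e5, 1e3), case[2], case[1]) > 0)
    expect_identical(ic$flag == "dominant", nb_all_pos)
  }
})
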
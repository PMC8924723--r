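# Synthetic parameter sets and known-truth scenarios.
#
# The three bundled model families need transition probabilities, costs and
# utilities. The generator below produces internally consistent, clearly
# synthetic sets: only the quantities with an agreed external anchor (the
# 8-unit per-use fee, the 3% discount rate, entry ages 50/12/40, the
# screening schedules, PPP rates) are fixed; every other magnitude is an
# invented plausible value with a seeded jitter and an accompanying 95% CI
# for probabilistic analysis. Nothing here reproduces any published tariff
# or transition table.

# symmetric CI half-width scaled like a binomial sd, keeps CIs inside (0,1)
.ci_prob <- function(m, width = 0.35) {
  w <- width * m * (1 - m)
  c(max(m - w, m / 2), min(m + w, m + (1 - m) / 2))
}
.ci_cost <- function(m) m * c(0.7, 1.35)

#' Generate a synthetic age-indexed life table
#'
#' Annual background death probabilities on a Gompertz hazard (exponentially
#' increasing with age), scaled per setting and forced to probability 1 at
#' the maximum age. The small seeded jitter makes distinct synthetic
#' populations reproducible.
#'
#' @param setting `"US"`, `"Germany"`, `"Brazil"` or `"generic"`.
#' @param seed Integer seed.
#' @param max_age Age at which death is certain (default 110).
#' @return Numeric vector of length `max_age + 1`: annual death probability
#'   at ages `0 .. max_age`, non-decreasing, ending in 1.
#' @export
generate_life_table <- function(setting = c("generic", "US", "Germany",
                                            "Brazil"),
                                seed = 1, max_age = 110) {
  setting <- match.arg(setting)
  a0 <- switch(setting, US = 6e-5, Germany = 5e-5, Brazil = 9e-5,
               generic = 7e-5)
  b <- 0.088
  set.seed(seed)
  a <- a0 * exp(stats::runif(1, -0.1, 0.1))
  ages <- 0:max_age
  q <- pmin(a * exp(b * ages), 1)
  q[length(q)] <- 1
  q
}

# invented baseline magnitudes per use case; jittered per seed below
.base_params <- list(
  dermatology = list(
    probs_beta = c(p_incidence = 0.004, p_symptom_detect = 0.30,
                   p_mel_death_undetected = 0.10,
                   p_mel_death_detected = 0.02, p_remission = 0.35,
                   p_recurrence = 0.02,
                   sens_ai = 0.85, spec_ai = 0.85,
                   sens_std = 0.76, spec_std = 0.84),
    probs_uniform = c(),
    costs = c(c_biopsy = 150, c_excision = 1200,
              c_treatment_annual = 2000, c_followup = 300),
    utils = c(u_undetected = 0.97, u_detected = 0.80, u_remission = 0.92),
    fixed = list(u_healthy = 1, fee = 8, schedule = 1, discount = 0.03,
                 entry_age = 50, max_age = 100),
    setting = "US"),
  dentistry = list(
    probs_beta = c(p_loss_untreated = 0.03, p_symptomatic_treat = 0.15,
                   p_restoration_failure = 0.06,
                   p_rerestoration_failure = 0.08, p_arrest = 0.30,
                   prev_initial = 0.20, prev_advanced = 0.08,
                   sens_ai = 0.75, spec_ai = 0.83,
                   sens_std = 0.40, spec_std = 0.91),
    probs_uniform = c(p_initiation = 0.03, p_progression = 0.08),
    costs = c(c_restoration = 90, c_rerestoration = 160,
              c_extraction = 250, c_noninvasive = 25),
    utils = c(),
    fixed = list(fee = 8, schedule = 2, discount = 0.03,
                 treatment_path = "noninvasive",
                 entry_age = 12, max_age = 83),
    setting = "Germany"),
  ophthalmology = list(
    probs_beta = c(p_onset = 0.06, p_progression = 0.10,
                   p_blind_untreated = 0.12, p_blind_treated = 0.02,
                   p_symptom_treat = 0.15,
                   prev_npdr = 0.15, prev_pdr = 0.05,
                   sens_ai = 0.87, spec_ai = 0.90,
                   sens_std = 0.80, spec_std = 0.95),
    probs_uniform = c(),
    costs = c(c_treatment = 1500, c_treated_annual = 200,
              c_pdr_annual = 150, c_blind_annual = 800, c_workup = 60,
              mort_mult_diabetes = 1.8, mort_mult_blind = 2.5),
    utils = c(u_nodr = 0.90, u_npdr = 0.85, u_pdr = 0.75,
              u_treated = 0.82, u_blind = 0.50),
    fixed = list(fee = 8, schedule = 0.5, discount = 0.03,
                 entry_age = 40, max_age = 100),
    setting = "Brazil"))

#' Generate a complete synthetic parameter and distribution set
#'
#' Emits everything one use-case model needs: a full parameter list
#' (transition probabilities, costs, utilities, accuracies, life table,
#' entry age, horizon, fee, schedule, discount rate) plus one uncertainty
#' distribution per sampled parameter (beta for probabilities and
#' utilities, gamma for costs, uniform for caries lesion initiation and
#' progression), each parameterised by its mean and a synthetic 95% CI.
#' Deterministic given the seed. Optionally written to a YAML config file
#' flagged `synthetic: true`.
#'
#' @param use_case `"dermatology"`, `"dentistry"` or `"ophthalmology"`.
#' @param seed Integer seed for the jitter on the invented magnitudes.
#' @param path Optional file path: write the result as a run config.
#' @return An object of class `synthetic_params`: list with `use_case`,
#'   `seed`, `synthetic = TRUE`, `params` (named list), `distributions`
#'   (list of [param_dist()]).
#' @export
generate_default_params <- function(use_case = c("dermatology", "dentistry",
                                                 "ophthalmology"),
                                    seed = 1, path = NULL) {
  use_case <- match.arg(use_case)
  base <- .base_params[[use_case]]
  set.seed(seed)
  jitter <- function(x) x * exp(stats::runif(length(x), -0.08, 0.08))
  probs <- jitter(base$probs_beta)
  probs <- pmin(probs, 0.995)
  unif <- jitter(base$probs_uniform)
  costs <- jitter(base$costs)
  utils_ <- pmin(jitter(base$utils), 0.99)

  params <- c(as.list(round(probs, 5)), as.list(round(unif, 5)),
              as.list(round(costs, 2)), as.list(round(utils_, 4)),
              base$fixed)
  params$life_table <- generate_life_table(base$setting, seed = seed)

  dists <- c(
    lapply(names(probs), function(nm)
      param_dist(nm, "beta", mean = params[[nm]],
                 ci = round(.ci_prob(params[[nm]]), 5))),
    lapply(names(unif), function(nm)
      param_dist(nm, "uniform",
                 ci = round(c(params[[nm]] * 0.5, params[[nm]] * 1.6), 5))),
    lapply(names(costs), function(nm)
      param_dist(nm, "gamma", mean = params[[nm]],
                 ci = round(.ci_cost(params[[nm]]), 2))),
    lapply(names(utils_), function(nm)
      param_dist(nm, "beta", mean = params[[nm]],
                 ci = round(.ci_prob(params[[nm]]), 4))))

  out <- structure(list(use_case = use_case, seed = seed, synthetic = TRUE,
                        params = params, distributions = dists),
                   class = "synthetic_params")
  if (!is.null(path)) write_config(as_run_config(out), path)
  out
}

#' Turn a synthetic parameter set into a full run configuration
#'
#' @param x A `synthetic_params` object.
#' @param n_psa,n_individuals,wtp_max,wtp_step Run settings recorded in the
#'   config.
#' @return A `run_config` list as produced by [load_config()].
#' @export
as_run_config <- function(x, n_psa = 1000, n_individuals = 1000,
                          wtp_max = 1e5, wtp_step = 1000) {
  stopifnot(inherits(x, "synthetic_params"))
  structure(list(synthetic = TRUE, use_case = x$use_case, seed = x$seed,
                 n_psa = n_psa, n_individuals = n_individuals,
                 discount = x$params$discount %||% 0.03,
                 wtp_max = wtp_max, wtp_step = wtp_step,
                 params = x$params, distributions = x$distributions),
            class = "run_config")
}

#' Generate a known-truth scenario with closed-form reference values
#'
#' Deliberately simple model instances whose expected discounted cost and
#' effect have closed forms (geometric and two-stage geometric series),
#' used to validate both the analytic cohort solver (agreement to 1e-9)
#' and the microsimulation (agreement within Monte Carlo error). Scenarios
#' are themed per use case: a two-state survival chain (dermatology), a
#' tooth present/lost chain with identical perfect-test screening arms
#' (dentistry), and a three-state well/impaired/dead chain with stage
#' utilities (ophthalmology).
#'
#' @param use_case `"dermatology"`, `"dentistry"` or `"ophthalmology"`.
#' @param seed Integer seed; drives the scenario's parameter draw.
#' @return List with `spec`, `rewards`, `arms` (possibly `NULL`),
#'   `params`, `discount_rate`, and `reference` — the closed-form expected
#'   `cost` and `effect` per individual.
#' @export
generate_known_truth_scenario <- function(use_case = c("dermatology",
                                                       "dentistry",
                                                       "ophthalmology"),
                                          seed = 1) {
  use_case <- match.arg(use_case)
  set.seed(seed)
  r <- sample(c(0, 0.03, 0.05), 1)
  d <- 1 / (1 + r)
  geo <- function(x) 1 / (1 - x)   # sum_{t>=0} x^t, |x| < 1

  if (use_case %in% c("dermatology", "dentistry")) {
    p <- stats::runif(1, 0.1, 0.4)
    cost_rate <- stats::runif(1, 50, 200)
    alive <- if (use_case == "dentistry") "Tooth present" else "Alive"
    dead <- if (use_case == "dentistry") "Tooth lost" else "Dead"
    spec <- markov_model(
      state_ids = c(alive, dead), absorbing = dead,
      entry_age = 0, entry_state_distribution = stats::setNames(1, alive),
      max_age = Inf,
      transition_fn = function(state, age, params, treated) {
        if (state == dead) stats::setNames(1, dead)
        else stats::setNames(c(1 - p, p), c(alive, dead))
      })
    rewards <- reward_spec(
      state_cost = stats::setNames(cost_rate, alive),
      state_effect = stats::setNames(1, alive),
      currency = "EUR",
      effect_unit = if (use_case == "dentistry") "tooth-retention-year"
                    else "QALY")
    E <- geo((1 - p) * d)            # expected discounted years alive
    arms <- NULL
    fee_cost <- 0
    if (use_case == "dentistry") {
      # identical perfect-specificity arms: screening accrues fees only
      fee <- stats::runif(1, 0, 10)
      mk <- function(label) screening_strategy(
        diagnostic_test(sensitivity = stats::setNames(numeric(0),
                                                      character(0)),
                        specificity = 1, fee = fee, label = label),
        schedule = 1,
        decisions = decision_map(c(alive, dead)))
      arms <- list(ai = mk("AI"), standard = mk("standard"))
      fee_cost <- fee * E
    }
    reference <- list(cost = cost_rate * E + fee_cost, effect = E)
    return(list(spec = spec, rewards = rewards, arms = arms,
                params = list(), discount_rate = r, reference = reference,
                use_case = use_case, seed = seed))
  }

  # three-state chain: Well -> Impaired -> Dead, stage utilities and costs
  a <- stats::runif(1, 0.1, 0.3)
  b <- stats::runif(1, 0.35, 0.6)    # disjoint from a: closed form needs a != b
  u <- c(Well = 1, Impaired = stats::runif(1, 0.3, 0.8))
  cost <- c(Well = stats::runif(1, 20, 80),
            Impaired = stats::runif(1, 200, 600))
  spec <- markov_model(
    state_ids = c("Well", "Impaired", "Dead"), absorbing = "Dead",
    entry_age = 0, entry_state_distribution = c(Well = 1), max_age = Inf,
    transition_fn = function(state, age, params, treated) {
      switch(state,
             Well = c(Well = 1 - a, Impaired = a),
             Impaired = c(Impaired = 1 - b, Dead = b),
             Dead = c(Dead = 1))
    })
  rewards <- reward_spec(state_cost = cost, state_effect = u,
                         currency = "BRL", effect_unit = "QALY")
  # occupancy sums: sum_t d^t o_W(t) and sum_t d^t o_I(t), with
  # o_W(t) = (1-a)^t and o_I(t) = a[(1-a)^t - (1-b)^t] / ((1-a) - (1-b))
  SW <- geo((1 - a) * d)
  SI <- a / ((1 - a) - (1 - b)) * (geo((1 - a) * d) - geo((1 - b) * d))
  reference <- list(cost = cost["Well"] * SW + cost["Impaired"] * SI,
                    effect = u["Well"] * SW + u["Impaired"] * SI)
  reference <- lapply(reference, unname)
  list(spec = spec, rewards = rewards, arms = NULL, params = list(),
       discount_rate = r, reference = reference,
       use_case = use_case, seed = seed)
}

#' Deterministic fee break-even toy model
#'
#' A minimal deterministic comparison for exercising fee sweeps and
#' threshold detection: an individual enters with a treatable condition and
#' lives exactly `n_tests` cycles. The AI arm detects at entry (perfect
#' sensitivity), avoiding a one-time late-treatment cost of
#' `treatment_savings` at the end of life, and is tested once per cycle at
#' the per-use fee; the standard arm never detects and pays the late cost.
#' Undiscounted, the AI arm's incremental cost is
#' `n_tests * fee - treatment_savings`, so dominance flips exactly at
#' `fee = treatment_savings / n_tests`.
#'
#' @param treatment_savings One-time cost avoided by early detection.
#' @param n_tests Lifetime number of test applications (= cycles lived).
#' @return A `use_case_model`-style handle (fields `label`, `build`,
#'   `params`) usable with [one_way_sweep()] and [find_threshold()].
#' @export
build_fee_threshold_toy <- function(treatment_savings = 64, n_tests = 4) {
  stopifnot(n_tests >= 1, treatment_savings > 0)
  build <- function(params) {
    states <- c("Disease", "Treated", "Dead")
    last <- n_tests - 1
    spec <- markov_model(
      state_ids = states, absorbing = "Dead",
      entry_age = 0, entry_state_distribution = c(Disease = 1),
      max_age = n_tests,
      transition_fn = function(state, age, p, treated) {
        switch(state,
               Disease = if (treated && age < last) c(Treated = 1)
                         else if (age >= last) c(Dead = 1)
                         else c(Disease = 1),
               Treated = if (age >= last) c(Dead = 1) else c(Treated = 1),
               Dead = c(Dead = 1))
      })
    rewards <- reward_spec(
      state_effect = c(Disease = 0.9, Treated = 1),
      event_cost = data.frame(from = "Disease", to = "Dead",
                              cost = params$treatment_savings),
      currency = "EUR", effect_unit = "QALY")
    decisions <- decision_map(states,
                              positive = c(Disease = "treat-invasive"))
    arms <- list(
      ai = screening_strategy(
        diagnostic_test(c(Disease = 1), specificity = 1,
                        fee = params$fee, label = "AI"),
        schedule = 1, decisions = decisions),
      standard = screening_strategy(
        diagnostic_test(c(Disease = 0), specificity = 1, fee = 0,
                        label = "standard"),
        schedule = 1, decisions = decisions))
    list(spec = spec, rewards = rewards, arms = arms)
  }
  structure(list(label = "fee-threshold toy", build = build,
                 params = list(fee = 8, discount = 0,
                               treatment_savings = treatment_savings)),
            class = "use_case_model")
}
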
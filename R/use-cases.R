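# The three concrete screening model families. Each builder maps a flat
# named parameter list to (markov_model, reward_spec, two screening arms).
# The state lists are defaults, not engine constraints: the engine accepts
# any well-formed model, so richer stagings are configuration-only changes.

# annual background death probability at `age` from a life-table vector
# (index age 0..length-1), with an optional hazard multiplier
.bg_q <- function(params, age, mult = 1) {
  lt <- params$life_table
  if (is.null(lt)) return(0)
  q <- lt[min(floor(age), length(lt) - 1) + 1]
  min(q * mult, 1)
}

.required_params <- function(params, needed, model) {
  missing <- setdiff(needed, names(params))
  if (length(missing) > 0)
    stop(model, ": missing parameters: ", paste(missing, collapse = ", "),
         call. = FALSE)
}

#' Build the melanoma screening model (dermatology)
#'
#' A general-population cohort entering in full health, at risk of
#' developing melanoma that may remain undetected (higher disease-specific
#' mortality), be detected by screening or symptoms (treatment, lower
#' mortality, possible remission with recurrence), or end in
#' melanoma-specific or background death. Disease-specific death competes
#' with background mortality: the melanoma transition is taken first and
#' background death applies to the survivors. The AI and dermatologist arms
#' differ only in test accuracy and per-use fee. Costs are in USD, effects
#' in QALYs.
#'
#' @param params Named list; required entries: `p_incidence`,
#'   `p_symptom_detect`, `p_mel_death_undetected`, `p_mel_death_detected`,
#'   `p_remission`, `p_recurrence`, `c_biopsy`, `c_excision`,
#'   `c_treatment_annual`, `c_followup`, `u_healthy`, `u_undetected`,
#'   `u_detected`, `u_remission`, `fee`, `schedule`, accuracy entries
#'   (`sens_ai`, `spec_ai`, `sens_std`, `spec_std`), `life_table`,
#'   `entry_age`, `max_age`.
#' @return List with `spec` ([markov_model()]), `rewards` ([reward_spec()])
#'   and `arms` (list of [screening_strategy()]: `ai`, `standard`).
#' @export
build_melanoma_model <- function(params) {
  .required_params(params, c(
    "p_incidence", "p_symptom_detect", "p_mel_death_undetected",
    "p_mel_death_detected", "p_remission", "p_recurrence",
    "c_biopsy", "c_excision", "c_treatment_annual", "c_followup",
    "u_healthy", "u_undetected", "u_detected", "u_remission",
    "fee", "schedule", "sens_ai", "spec_ai", "sens_std", "spec_std",
    "life_table", "entry_age", "max_age"), "melanoma model")
  states <- c("Healthy", "Undetected melanoma", "Detected melanoma",
              "Remission", "Melanoma death", "Other death")
  transition_fn <- function(state, age, p, treated) {
    q <- .bg_q(p, age)
    row <- switch(
      state,
      "Healthy" = c("Healthy" = 1 - p$p_incidence,
                    "Undetected melanoma" = p$p_incidence),
      "Undetected melanoma" = if (treated) {
        # screening detection routes straight to treatment
        c("Detected melanoma" = 1)
      } else {
        c("Melanoma death" = p$p_mel_death_undetected,
          "Detected melanoma" =
            (1 - p$p_mel_death_undetected) * p$p_symptom_detect,
          "Undetected melanoma" =
            (1 - p$p_mel_death_undetected) * (1 - p$p_symptom_detect))
      },
      "Detected melanoma" = c(
        "Melanoma death" = p$p_mel_death_detected,
        "Remission" = (1 - p$p_mel_death_detected) * p$p_remission,
        "Detected melanoma" =
          (1 - p$p_mel_death_detected) * (1 - p$p_remission)),
      "Remission" = c("Detected melanoma" = p$p_recurrence,
                      "Remission" = 1 - p$p_recurrence),
      "Melanoma death" = c("Melanoma death" = 1),
      "Other death" = c("Other death" = 1))
    if (!state %in% c("Melanoma death", "Other death"))
      row <- add_background_mortality(row, q, "Other death",
                                      exempt = "Melanoma death")
    row
  }
  spec <- markov_model(
    state_ids = states,
    absorbing = c("Melanoma death", "Other death"),
    entry_age = params$entry_age,
    entry_state_distribution = c("Healthy" = 1),
    max_age = params$max_age,
    transition_fn = transition_fn)
  rewards <- reward_spec(
    state_cost = c("Detected melanoma" = params$c_treatment_annual,
                   "Remission" = params$c_followup),
    state_effect = c("Healthy" = params$u_healthy,
                     "Undetected melanoma" = params$u_undetected,
                     "Detected melanoma" = params$u_detected,
                     "Remission" = params$u_remission),
    event_cost = data.frame(from = "Undetected melanoma",
                            to = "Detected melanoma",
                            cost = params$c_excision),
    action_cost = c("refer" = params$c_biopsy),
    currency = "USD", effect_unit = "QALY")
  decisions <- decision_map(
    states,
    positive = c("Healthy" = "refer",              # false positive: biopsy
                 "Undetected melanoma" = "treat-invasive",
                 "Detected melanoma" = "monitor",
                 "Remission" = "monitor"))
  arms <- list(
    ai = screening_strategy(
      diagnostic_test(c("Undetected melanoma" = params$sens_ai),
                      params$spec_ai, fee = params$fee, label = "AI"),
      schedule = params$schedule, decisions = decisions),
    standard = screening_strategy(
      diagnostic_test(c("Undetected melanoma" = params$sens_std),
                      params$spec_std, fee = 0, label = "standard"),
      schedule = params$schedule, decisions = decisions))
  list(spec = spec, rewards = rewards, arms = arms)
}

#' Build the proximal caries model (dentistry, tooth level)
#'
#' The unit of analysis is a single tooth followed from age 12 over the
#' host's remaining lifetime. Sound teeth may develop initial lesions that
#' progress to advanced lesions and, untreated, toward loss; restorations
#' survive, fail into re-restoration/endodontic treatment and eventually
#' extraction. The effect is one tooth-retention-year per cycle while the
#' tooth is present. `treatment_path` switches what a detected initial
#' lesion triggers: `"noninvasive"` management (arrest attempt, the tooth
#' stays unrestored) or `"invasive"` immediate restoration — under which a
#' false positive on a sound tooth is restored too (overtreatment enters
#' the restoration chain). Costs are in EUR.
#'
#' @param params Named list; required entries: `p_initiation`,
#'   `p_progression`, `p_loss_untreated`, `p_symptomatic_treat`,
#'   `p_restoration_failure`, `p_rerestoration_failure`, `p_arrest`,
#'   `prev_initial`, `prev_advanced`, `c_restoration`, `c_rerestoration`,
#'   `c_extraction`, `c_noninvasive`, `fee`, `schedule`, accuracies,
#'   `treatment_path`, `entry_age`, `max_age`.
#' @return As [build_melanoma_model()].
#' @export
build_caries_model <- function(params) {
  .required_params(params, c(
    "p_initiation", "p_progression", "p_loss_untreated",
    "p_symptomatic_treat", "p_restoration_failure",
    "p_rerestoration_failure", "p_arrest", "prev_initial", "prev_advanced",
    "c_restoration", "c_rerestoration", "c_extraction", "c_noninvasive",
    "fee", "schedule", "sens_ai", "spec_ai", "sens_std", "spec_std",
    "treatment_path", "entry_age", "max_age"), "caries model")
  if (!params$treatment_path %in% c("invasive", "noninvasive"))
    stop("caries model: treatment_path must be 'invasive' or 'noninvasive'",
         call. = FALSE)
  invasive <- params$treatment_path == "invasive"
  states <- c("Sound", "Initial lesion", "Advanced lesion", "Restored",
              "Re-restored", "Tooth lost")
  transition_fn <- function(state, age, p, treated) {
    inv <- p$treatment_path == "invasive"
    switch(
      state,
      "Sound" = if (treated && inv) {
        c("Restored" = 1)                      # overtreated false positive
      } else {
        c("Sound" = 1 - p$p_initiation, "Initial lesion" = p$p_initiation)
      },
      "Initial lesion" = if (treated && inv) {
        c("Restored" = 1)
      } else if (treated) {
        c("Sound" = p$p_arrest, "Initial lesion" = 1 - p$p_arrest)
      } else {
        c("Advanced lesion" = p$p_progression,
          "Initial lesion" = 1 - p$p_progression)
      },
      "Advanced lesion" = if (treated) {
        c("Restored" = 1)
      } else {
        c("Tooth lost" = p$p_loss_untreated,
          "Restored" = (1 - p$p_loss_untreated) * p$p_symptomatic_treat,
          "Advanced lesion" =
            (1 - p$p_loss_untreated) * (1 - p$p_symptomatic_treat))
      },
      "Restored" = c("Re-restored" = p$p_restoration_failure,
                     "Restored" = 1 - p$p_restoration_failure),
      "Re-restored" = c("Tooth lost" = p$p_rerestoration_failure,
                        "Re-restored" = 1 - p$p_rerestoration_failure),
      "Tooth lost" = c("Tooth lost" = 1))
  }
  spec <- markov_model(
    state_ids = states,
    absorbing = "Tooth lost",
    entry_age = params$entry_age,
    entry_state_distribution = c(
      "Sound" = 1 - params$prev_initial - params$prev_advanced,
      "Initial lesion" = params$prev_initial,
      "Advanced lesion" = params$prev_advanced),
    max_age = params$max_age,
    transition_fn = transition_fn)
  rewards <- reward_spec(
    state_effect = c("Sound" = 1, "Initial lesion" = 1,
                     "Advanced lesion" = 1, "Restored" = 1,
                     "Re-restored" = 1),
    event_cost = data.frame(
      from = c("Sound", "Initial lesion", "Advanced lesion", "Restored",
               "Re-restored", "Advanced lesion"),
      to = c("Restored", "Restored", "Restored", "Re-restored",
             "Tooth lost", "Tooth lost"),
      cost = c(params$c_restoration, params$c_restoration,
               params$c_restoration, params$c_rerestoration,
               params$c_extraction, params$c_extraction)),
    action_cost = c("treat-noninvasive" = params$c_noninvasive),
    currency = "EUR", effect_unit = "tooth-retention-year")
  decisions <- decision_map(
    states,
    positive = c(
      "Sound" = if (invasive) "treat-invasive" else "monitor",
      "Initial lesion" = if (invasive) "treat-invasive"
                         else "treat-noninvasive",
      "Advanced lesion" = "treat-invasive"))
  arms <- list(
    ai = screening_strategy(
      diagnostic_test(
        sensitivity = params$sens_ai, specificity = params$spec_ai,
        fee = params$fee, label = "AI",
        diseased = c("Initial lesion", "Advanced lesion")),
      schedule = params$schedule, decisions = decisions),
    standard = screening_strategy(
      diagnostic_test(
        sensitivity = params$sens_std, specificity = params$spec_std,
        fee = 0, label = "standard",
        diseased = c("Initial lesion", "Advanced lesion")),
      schedule = params$schedule, decisions = decisions))
  list(spec = spec, rewards = rewards, arms = arms)
}

#' Build the diabetic retinopathy model (ophthalmology)
#'
#' A diabetic cohort entering at age 40, screened every other year by
#' default. Retinopathy develops (non-proliferative), may progress to a
#' proliferative/sight-threatening stage, and untreated can end in
#' blindness; detection at the sight-threatening stage triggers treatment
#' that greatly lowers the blindness risk. Retinopathy itself is non-lethal:
#' death occurs only through (diabetes-elevated) background mortality, so
#' blindness is clinically absorbing — no recovery, utility keeps accruing
#' until death. Per-state utilities weight each cycle's effect. Costs are in
#' BRL, effects in QALYs.
#'
#' @param params Named list; required entries: `p_onset`, `p_progression`,
#'   `p_blind_untreated`, `p_blind_treated`, `p_symptom_treat`,
#'   `mort_mult_diabetes`, `mort_mult_blind`, `c_treatment`,
#'   `c_treated_annual`, `c_pdr_annual`, `c_blind_annual`, `c_workup`,
#'   utilities (`u_nodr`, `u_npdr`, `u_pdr`, `u_treated`, `u_blind`),
#'   `fee`, `schedule`, accuracies, `life_table`, `entry_age`, `max_age`.
#' @return As [build_melanoma_model()].
#' @export
build_retinopathy_model <- function(params) {
  .required_params(params, c(
    "p_onset", "p_progression", "p_blind_untreated", "p_blind_treated",
    "p_symptom_treat", "mort_mult_diabetes", "mort_mult_blind",
    "c_treatment", "c_treated_annual", "c_pdr_annual", "c_blind_annual",
    "c_workup", "u_nodr", "u_npdr", "u_pdr", "u_treated", "u_blind",
    "prev_npdr", "prev_pdr",
    "fee", "schedule", "sens_ai", "spec_ai", "sens_std", "spec_std",
    "life_table", "entry_age", "max_age"), "retinopathy model")
  utils_ <- unlist(params[c("u_nodr", "u_npdr", "u_pdr", "u_treated",
                            "u_blind")])
  if (any(utils_ < 0 | utils_ > 1))
    stop("retinopathy model: utilities must lie in [0, 1]", call. = FALSE)
  states <- c("No DR", "Nonproliferative DR", "Proliferative DR",
              "Treated DR", "Blindness", "Death")
  transition_fn <- function(state, age, p, treated) {
    if (state == "Death") return(c("Death" = 1))
    mult <- if (state == "Blindness") p$mort_mult_blind
            else p$mort_mult_diabetes
    q <- .bg_q(p, age, mult)
    row <- switch(
      state,
      "No DR" = c("No DR" = 1 - p$p_onset,
                  "Nonproliferative DR" = p$p_onset),
      "Nonproliferative DR" = c(
        "Nonproliferative DR" = 1 - p$p_progression,
        "Proliferative DR" = p$p_progression),
      "Proliferative DR" = if (treated) {
        c("Treated DR" = 1)
      } else {
        c("Blindness" = p$p_blind_untreated,
          "Treated DR" = (1 - p$p_blind_untreated) * p$p_symptom_treat,
          "Proliferative DR" =
            (1 - p$p_blind_untreated) * (1 - p$p_symptom_treat))
      },
      "Treated DR" = c("Blindness" = p$p_blind_treated,
                       "Treated DR" = 1 - p$p_blind_treated),
      "Blindness" = c("Blindness" = 1))
    add_background_mortality(row, q, "Death")
  }
  spec <- markov_model(
    state_ids = states,
    absorbing = "Death",
    entry_age = params$entry_age,
    entry_state_distribution = c(
      "No DR" = 1 - params$prev_npdr - params$prev_pdr,
      "Nonproliferative DR" = params$prev_npdr,
      "Proliferative DR" = params$prev_pdr),
    max_age = params$max_age,
    transition_fn = transition_fn)
  rewards <- reward_spec(
    state_cost = c("Proliferative DR" = params$c_pdr_annual,
                   "Treated DR" = params$c_treated_annual,
                   "Blindness" = params$c_blind_annual),
    state_effect = c("No DR" = params$u_nodr,
                     "Nonproliferative DR" = params$u_npdr,
                     "Proliferative DR" = params$u_pdr,
                     "Treated DR" = params$u_treated,
                     "Blindness" = params$u_blind),
    event_cost = data.frame(
      from = "Proliferative DR", to = "Treated DR",
      cost = params$c_treatment),
    action_cost = c("refer" = params$c_workup),
    currency = "BRL", effect_unit = "QALY")
  decisions <- decision_map(
    states,
    positive = c("No DR" = "refer",            # false positive: work-up
                 "Nonproliferative DR" = "monitor",
                 "Proliferative DR" = "treat-invasive"))
  mk_test <- function(sens, spec_, fee, label)
    diagnostic_test(sensitivity = sens, specificity = spec_, fee = fee,
                    label = label,
                    diseased = c("Nonproliferative DR", "Proliferative DR"))
  arms <- list(
    ai = screening_strategy(mk_test(params$sens_ai, params$spec_ai,
                                    params$fee, "AI"),
                            schedule = params$schedule,
                            decisions = decisions),
    standard = screening_strategy(mk_test(params$sens_std, params$spec_std,
                                          0, "standard"),
                                  schedule = params$schedule,
                                  decisions = decisions))
  list(spec = spec, rewards = rewards, arms = arms)
}

#' Bundle a use-case builder with its parameters
#'
#' The handle passed to [run_psa()] and [one_way_sweep()]: a builder
#' function plus the current parameter list, so sweeps and probabilistic
#' replicates can rebuild the model under perturbed parameters.
#'
#' @param use_case `"dermatology"`, `"dentistry"` or `"ophthalmology"`.
#' @param params Parameter list for the corresponding builder; defaults to
#'   the synthetic set from [generate_default_params()] (seed 1).
#' @return An object of class `use_case_model` with fields `label`,
#'   `build`, `params`.
#' @export
use_case_model <- function(use_case = c("dermatology", "dentistry",
                                        "ophthalmology"),
                           params = NULL) {
  use_case <- match.arg(use_case)
  build <- switch(use_case,
                  dermatology = build_melanoma_model,
                  dentistry = build_caries_model,
                  ophthalmology = build_retinopathy_model)
  if (is.null(params))
    params <- generate_default_params(use_case, seed = 1)$params
  structure(list(label = use_case, build = build, params = params),
            class = "use_case_model")
}
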
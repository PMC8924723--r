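# Small models built in code, shared across test files.

# two-state survival chain: Alive -> Dead with constant annual probability p
two_state_model <- function(p, cost_rate = 0, effect_rate = 1,
                            max_age = Inf) {
  spec <- markov_model(
    state_ids = c("Alive", "Dead"), absorbing = "Dead",
    entry_age = 0, entry_state_distribution = c(Alive = 1),
    max_age = max_age,
    transition_fn = function(state, age, params, treated) {
      if (state == "Dead") c(Dead = 1) else c(Alive = 1 - p, Dead = p)
    })
  rewards <- reward_spec(state_cost = c(Alive = cost_rate),
                         state_effect = c(Alive = effect_rate))
  list(spec = spec, rewards = rewards)
}

# survival under an age-indexed life table, for age-dependent transitions
life_table_model <- function(life_table, entry_age, max_age = 111) {
  spec <- markov_model(
    state_ids = c("Alive", "Dead"), absorbing = "Dead",
    entry_age = entry_age, entry_state_distribution = c(Alive = 1),
    max_age = max_age,
    transition_fn = function(state, age, params, treated) {
      if (state == "Dead") return(c(Dead = 1))
      q <- life_table[min(age, length(life_table) - 1) + 1]
      c(Alive = 1 - q, Dead = q)
    })
  rewards <- reward_spec(state_effect = c(Alive = 1))
  list(spec = spec, rewards = rewards)
}

# a dentistry model variant with both arms set to the same test and fee,
# so the two arms must coincide under common random numbers
identical_arm_params <- function(use_case, seed = 1) {
  pars <- generate_default_params(use_case, seed = seed)$params
  pars$fee <- 0
  pars$sens_std <- pars$sens_ai
  pars$spec_std <- pars$spec_ai
  pars
}

# brute-force acceptability: per-draw counting, independent of ceac()
ceac_oracle <- function(draws, wtp) {
  de <- draws$effect_ai - draws$effect_std
  dc <- draws$cost_ai - draws$cost_std
  vapply(wtp, function(w) {
    pos <- 0
    for (i in seq_len(nrow(draws))) {
      nb <- w * de[i] - dc[i]
      if (nb > 0) pos <- pos + 1
      else if (nb == 0) pos <- pos + 0.5
    }
    pos / nrow(draws)
  }, numeric(1))
}
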
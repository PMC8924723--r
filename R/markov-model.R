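#' Define a discrete-time Markov state-transition model
#'
#' A `markov_model` holds the state space, the absorbing states, the entry
#' conditions and the transition rule of an annual-cycle state-transition
#' model. Transition probabilities may depend on age and on a screening
#' decision taken earlier in the same cycle (the `treated` flag), which is how
#' detection routes individuals onto a treated branch of the natural history.
#'
#' @param state_ids Character vector of state labels, in a fixed order.
#' @param absorbing Character vector, subset of `state_ids`: states that,
#'   once entered, are never left (self-transition probability 1).
#' @param entry_age Age (years) at which individuals enter the model.
#' @param entry_state_distribution Named probability vector over `state_ids`
#'   (missing states get probability 0). Must sum to 1.
#' @param max_age Horizon bound: the simulation stops once age reaches
#'   `max_age`. May be `Inf` when every trajectory is guaranteed to reach a
#'   zero-reward absorbing state.
#' @param transition_fn Function `(state, age, params, treated)` returning a
#'   named probability vector over `state_ids` (names may be a subset;
#'   missing targets get 0). `treated` is `TRUE` in cycles where the
#'   screening decision mapped to a treatment action.
#' @return An object of class `markov_model`.
#' @seealso [validate_model()], [simulate_cohort()], [solve_cohort_analytic()]
#' @export
markov_model <- function(state_ids, absorbing = character(), entry_age,
                         entry_state_distribution, max_age = Inf,
                         transition_fn) {
  stopifnot(is.character(state_ids), length(state_ids) >= 1,
            !anyDuplicated(state_ids),
            all(absorbing %in% state_ids),
            is.function(transition_fn),
            is.numeric(entry_age), length(entry_age) == 1, entry_age >= 0,
            is.numeric(max_age), length(max_age) == 1, max_age > entry_age)
  entry <- .full_prob_vector(entry_state_distribution, state_ids,
                             what = "entry_state_distribution")
  structure(
    list(state_ids = state_ids,
         absorbing = absorbing,
         entry_age = entry_age,
         entry_state_distribution = entry,
         max_age = max_age,
         transition_fn = transition_fn),
    class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat("<markov_model>\n")
  cat("  states:    ", paste(x$state_ids, collapse = ", "), "\n")
  cat("  absorbing: ", paste(x$absorbing, collapse = ", "), "\n")
  cat("  entry age: ", x$entry_age, "  horizon: to age ", x$max_age, "\n",
      sep = "")
  invisible(x)
}

# expand a possibly-partial named vector to the full state order
.full_prob_vector <- function(p, state_ids, what = "probability vector") {
  out <- stats::setNames(numeric(length(state_ids)), state_ids)
  if (is.null(names(p))) {
    if (length(p) != length(state_ids))
      stop(what, " must be named or have one entry per state", call. = FALSE)
    out[] <- p
  } else {
    unknown <- setdiff(names(p), state_ids)
    if (length(unknown) > 0)
      stop(what, " names unknown states: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    out[names(p)] <- p
  }
  out
}

#' Per-state and per-transition rewards
#'
#' Costs and effects accrued while occupying states (per cycle) and when
#' making specific transitions (one-time event rewards), plus one-time costs
#' attached to screening decision actions (e.g. the work-up triggered by a
#' positive test). Effects are in QALYs or tooth-retention-years depending on
#' the model; the unit is carried as a tag. Absorbing end states (death,
#' tooth loss) conventionally accrue zero effect per cycle; states like
#' established blindness may be configured to keep accruing utility.
#'
#' @param state_cost Named money-per-cycle vector by state (missing = 0).
#' @param state_effect Named effect-per-cycle vector by state (missing = 0).
#' @param event_cost Optional data frame with columns `from`, `to`, `cost`:
#'   one-time cost accrued when that transition is made.
#' @param event_effect Optional data frame with columns `from`, `to`,
#'   `effect`.
#' @param action_cost Optional named money vector by decision action
#'   (see [decision_map()]), accrued once per test application that maps to
#'   that action.
#' @param currency Currency tag, uniform within one reward spec.
#' @param effect_unit `"QALY"` or `"tooth-retention-year"` (free text).
#' @return An object of class `reward_spec`.
#' @export
reward_spec <- function(state_cost = NULL, state_effect = NULL,
                        event_cost = NULL, event_effect = NULL,
                        action_cost = NULL,
                        currency = "EUR", effect_unit = "QALY") {
  chk_named <- function(x, what) {
    if (is.null(x)) return(x)
    stopifnot(is.numeric(x))
    if (is.null(names(x)) || any(names(x) == ""))
      stop(what, " must be a fully named numeric vector", call. = FALSE)
    if (any(!is.finite(x))) stop(what, " must be finite", call. = FALSE)
    x
  }
  chk_events <- function(x, col, what) {
    if (is.null(x)) return(x)
    stopifnot(is.data.frame(x), all(c("from", "to", col) %in% names(x)))
    if (any(!is.finite(x[[col]]))) stop(what, " must be finite", call. = FALSE)
    x
  }
  structure(
    list(state_cost = chk_named(state_cost, "state_cost"),
         state_effect = chk_named(state_effect, "state_effect"),
         event_cost = chk_events(event_cost, "cost", "event_cost"),
         event_effect = chk_events(event_effect, "effect", "event_effect"),
         action_cost = chk_named(action_cost, "action_cost"),
         currency = currency, effect_unit = effect_unit),
    class = "reward_spec")
}

# dense reward lookups aligned to the state order
.reward_vectors <- function(rewards, state_ids) {
  get_vec <- function(x) {
    out <- stats::setNames(numeric(length(state_ids)), state_ids)
    if (!is.null(x)) out[intersect(names(x), state_ids)] <-
        x[intersect(names(x), state_ids)]
    out
  }
  get_mat <- function(df, col) {
    m <- matrix(0, length(state_ids), length(state_ids),
                dimnames = list(state_ids, state_ids))
    if (!is.null(df) && nrow(df) > 0)
      m[cbind(match(df$from, state_ids), match(df$to, state_ids))] <- df[[col]]
    m
  }
  list(state_cost = get_vec(rewards$state_cost),
       state_effect = get_vec(rewards$state_effect),
       event_cost = if (is.null(rewards$event_cost)) NULL
                    else get_mat(rewards$event_cost, "cost"),
       event_effect = if (is.null(rewards$event_effect)) NULL
                      else get_mat(rewards$event_effect, "effect"))
}

# full transition matrix at one age; rows ordered like spec$state_ids
.transition_matrix <- function(spec, age, params, treated = FALSE) {
  S <- length(spec$state_ids)
  P <- matrix(0, S, S, dimnames = list(spec$state_ids, spec$state_ids))
  for (s in spec$state_ids) {
    row <- spec$transition_fn(s, age, params, treated)
    P[s, ] <- .full_prob_vector(row, spec$state_ids,
                                what = paste0("transition row for '", s, "'"))
  }
  P
}

#' Validate a Markov model against its structural invariants
#'
#' Checks, for every state and every age on the model's age grid, that
#' transition rows are non-negative and sum to 1 (within 1e-9), that
#' absorbing states self-transition with probability 1, and that the entry
#' distribution is a proper probability vector. Violations are returned as
#' data, not raised.
#'
#' @param spec A [markov_model()].
#' @param params Parameter list passed through to the transition function.
#' @param ages Ages to check; defaults to the model's whole age grid
#'   (capped at 120 cycles for unbounded horizons).
#' @return A character vector of violation messages; empty if the model is
#'   well formed. Each message names the state, the age and the broken rule.
#' @export
validate_model <- function(spec, params = list(), ages = NULL) {
  stopifnot(inherits(spec, "markov_model"))
  viol <- character()
  ed <- spec$entry_state_distribution
  if (any(ed < 0))
    viol <- c(viol, "entry_state_distribution: negative entries")
  if (abs(sum(ed) - 1) > 1e-9)
    viol <- c(viol, sprintf("entry_state_distribution: sums to %.10g, not 1",
                            sum(ed)))
  if (is.null(ages)) {
    last <- if (is.finite(spec$max_age)) spec$max_age - 1
            else spec$entry_age + 119
    ages <- seq(spec$entry_age, max(spec$entry_age, last))
  }
  for (age in ages) {
    for (treated in c(FALSE, TRUE)) {
      P <- tryCatch(.transition_matrix(spec, age, params, treated),
                    error = function(e) e)
      if (inherits(P, "error")) {
        viol <- c(viol, sprintf("age %s (treated=%s): %s", age, treated,
                                conditionMessage(P)))
        next
      }
      for (s in spec$state_ids) {
        row <- stats::setNames(P[s, ], spec$state_ids)
        if (any(row < 0))
          viol <- c(viol, sprintf(
            "state '%s', age %s (treated=%s): negative transition probability",
            s, age, treated))
        if (abs(sum(row) - 1) > 1e-9)
          viol <- c(viol, sprintf(
            "state '%s', age %s (treated=%s): row sums to %.10g, not 1",
            s, age, treated, sum(row)))
        if (s %in% spec$absorbing && abs(row[s] - 1) > 1e-9)
          viol <- c(viol, sprintf(
            "absorbing state '%s', age %s: self-probability %.10g, not 1",
            s, age, row[s]))
      }
    }
  }
  unique(viol)
}

#' Compose a disease transition row with background mortality
#'
#' Treats background (all-cause, non-disease) death as a competing event:
#' the disease transition happens first, then background death with annual
#' probability `q` is applied to individuals not already routed to a death
#' state. Exempt states (disease-specific death, other background-immune
#' targets) keep their probability mass.
#'
#' @param probs Named transition probability vector (disease level).
#' @param q Annual background death probability at the current age.
#' @param death_state Name of the background-death target state.
#' @param exempt Additional target states not subject to background death
#'   (e.g. a disease-specific death state). `death_state` is always exempt.
#' @return A named probability vector including the background death mass.
#' @export
add_background_mortality <- function(probs, q, death_state,
                                     exempt = character()) {
  stopifnot(is.numeric(q), length(q) == 1, q >= 0, q <= 1)
  exempt <- union(death_state, exempt)
  out <- probs
  if (!death_state %in% names(out)) out[death_state] <- 0
  live <- setdiff(names(out), exempt)
  moved <- sum(out[live]) * q
  out[live] <- out[live] * (1 - q)
  out[death_state] <- out[death_state] + moved
  out
}

#' Discount a cost or effect accrued after a number of years
#'
#' Standard annual discounting: `amount / (1 + rate)^years_elapsed`. The
#' entry year (cycle 0) is undiscounted.
#'
#' @param amount Money or effect amount (vectorised).
#' @param rate Per-annum discount rate in `[0, 1]` (default 3%).
#' @param years_elapsed Whole years since model entry; must be >= 0.
#' @return The discounted amount.
#' @export
discount <- function(amount, rate = 0.03, years_elapsed) {
  stopifnot(is.numeric(rate), all(rate >= 0), all(rate <= 1))
  if (any(years_elapsed < 0)) stop("years_elapsed must be >= 0", call. = FALSE)
  amount / (1 + rate)^years_elapsed
}
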
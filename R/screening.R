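#' Imperfect diagnostic test
#'
#' A test applied to an individual's (or tooth's) true state. States listed
#' in `sensitivity` are the diseased, detectable states: the test is positive
#' there with the given per-state probability. In every other state the test
#' is positive with probability `1 - specificity` (a false positive);
#' `specificity` may be a single value or named per state.
#'
#' @param sensitivity Named probability vector: diseased state -> P(positive).
#'   A single unnamed value may be given together with `diseased`.
#' @param specificity Single probability, or named vector per non-diseased
#'   state (unnamed value used as the default for all non-diseased states).
#' @param fee Money charged per test application (the per-use fee of an AI
#'   decision-support system, or 0 for conventional assessment).
#' @param label Arm name, e.g. `"AI"` or `"standard"`.
#' @param diseased States the unnamed scalar `sensitivity` applies to.
#' @return An object of class `diagnostic_test`.
#' @export
diagnostic_test <- function(sensitivity, specificity, fee = 0,
                            label = "test", diseased = NULL) {
  if (is.null(names(sensitivity))) {
    if (is.null(diseased))
      stop("unnamed sensitivity requires `diseased` state labels",
           call. = FALSE)
    sensitivity <- stats::setNames(rep_len(sensitivity, length(diseased)),
                                   diseased)
  }
  stopifnot(all(sensitivity >= 0 & sensitivity <= 1),
            all(specificity >= 0 & specificity <= 1),
            is.numeric(fee), length(fee) == 1, fee >= 0)
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 fee = fee, label = label),
            class = "diagnostic_test")
}

# P(positive result | true state), aligned to the model's state order
.positive_prob <- function(test, state_ids) {
  p <- stats::setNames(numeric(length(state_ids)), state_ids)
  spec <- test$specificity
  if (is.null(names(spec))) {
    p[] <- 1 - spec[1]
  } else {
    default <- if (any(names(spec) == "")) spec[names(spec) == ""][1] else NA
    for (s in state_ids) {
      if (s %in% names(spec)) p[s] <- 1 - spec[s]
      else if (!is.na(default)) p[s] <- 1 - default
      else p[s] <- NA_real_
    }
  }
  dis <- intersect(names(test$sensitivity), state_ids)
  p[dis] <- test$sensitivity[dis]
  if (anyNA(p))
    stop("states without a sensitivity or specificity entry: ",
         paste(state_ids[is.na(p)], collapse = ", "), call. = FALSE)
  p
}

#' Classify one individual's true state with an imperfect test
#'
#' Draws a single test result: positive with probability equal to the test's
#' sensitivity in a diseased state and `1 - specificity` otherwise.
#'
#' @param true_state State label the tested individual occupies.
#' @param test A [diagnostic_test()].
#' @param state_ids Optional full state list (for validation of coverage);
#'   defaults to the states named by the test.
#' @return `"positive"` or `"negative"`.
#' @export
classify <- function(true_state, test, state_ids = NULL) {
  ids <- if (is.null(state_ids)) union(names(test$sensitivity), true_state)
         else state_ids
  p <- .positive_prob(test, ids)
  if (!true_state %in% ids)
    stop("state '", true_state, "' has no accuracy entry", call. = FALSE)
  if (stats::runif(1) < p[true_state]) "positive" else "negative"
}

.actions <- c("treat-invasive", "treat-noninvasive", "refer", "monitor",
              "none")
# actions that put the individual on the treated transition branch
.treat_actions <- c("treat-invasive", "treat-noninvasive")

#' Map test results to clinical actions
#'
#' Builds the total decision map of a screening strategy: for each (result,
#' occupied state) pair, the action taken. Actions `treat-invasive` and
#' `treat-noninvasive` route the individual onto the treated branch of the
#' transition function for this cycle; `refer` and `monitor` may carry a
#' one-time work-up cost (see `action_cost` in [reward_spec()]) but do not
#' alter transitions; `none` does nothing.
#'
#' @param states Character vector of all model states.
#' @param positive,negative Named character vectors state -> action for the
#'   respective result; unspecified states get `default`.
#' @param default Action for unspecified (result, state) pairs.
#' @return A 2 x n-states character matrix with rows `positive`, `negative`.
#' @export
decision_map <- function(states, positive = character(),
                         negative = character(), default = "none") {
  m <- matrix(default, nrow = 2, ncol = length(states),
              dimnames = list(c("positive", "negative"), states))
  fill <- function(row, x) {
    if (length(x) == 0) return()
    bad <- setdiff(names(x), states)
    if (length(bad) > 0)
      stop("decision_map: unknown states ", paste(bad, collapse = ", "),
           call. = FALSE)
    m[row, names(x)] <<- x
  }
  fill("positive", positive)
  fill("negative", negative)
  if (!all(m %in% .actions))
    stop("decision_map: unknown actions ",
         paste(setdiff(m, .actions), collapse = ", "),
         "; known actions are ", paste(.actions, collapse = ", "),
         call. = FALSE)
  m
}

#' Screening strategy (one comparison arm)
#'
#' Couples a diagnostic test with a testing schedule and a decision map.
#' One strategy per arm: the AI-assisted arm and the standard-of-care arm of
#' a comparison typically differ only in test accuracy and per-use fee.
#'
#' @param test A [diagnostic_test()].
#' @param schedule Test applications per year. May be fractional: `0.5`
#'   means one test every 2 years, deterministically aligned to model entry.
#' @param decisions A decision map from [decision_map()] covering all states.
#' @param label Arm label; defaults to the test's label.
#' @return An object of class `screening_strategy`.
#' @export
screening_strategy <- function(test, schedule, decisions, label = NULL) {
  stopifnot(inherits(test, "diagnostic_test"),
            is.numeric(schedule), length(schedule) == 1, schedule > 0,
            is.matrix(decisions),
            identical(rownames(decisions), c("positive", "negative")))
  structure(list(test = test, schedule = schedule, decisions = decisions,
                 label = label %||% test$label),
            class = "screening_strategy")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of test applications due in a cycle
#'
#' Deterministic calendar: with schedule `s` per year, cycle `t` receives
#' `floor(s * (t + 1)) - floor(s * t)` applications, so `s = 2` gives two
#' tests every cycle and `s = 0.5` one test every other cycle starting at
#' entry.
#'
#' @param schedule Tests per year (> 0; may be fractional).
#' @param cycle_index Cycle number, 0-based (vectorised).
#' @return Integer count of test applications in that cycle.
#' @export
schedule_tests <- function(schedule, cycle_index) {
  stopifnot(schedule > 0, all(cycle_index >= 0))
  # tests fall at times 0, 1/s, 2/s, ... from entry; count those in [t, t+1)
  as.integer(ceiling(schedule * (cycle_index + 1) - 1e-9) -
             ceiling(schedule * cycle_index - 1e-9))
}

#' Resolve one test result into an action, fee and transition modifier
#'
#' Looks up the decision map of a strategy for a single (result, state) pair
#' and returns the mapped action, the fee accrued by the application, and
#' whether the individual is routed to the treated transition branch this
#' cycle. True positives in diseased states route to treatment; false
#' negatives leave the natural history untouched; false positives incur any
#' configured work-up/overtreatment cost downstream.
#'
#' @param result `"positive"` or `"negative"`.
#' @param true_state Occupied state label.
#' @param strategy A [screening_strategy()].
#' @return List with `action`, `fee`, and logical `treated`.
#' @export
apply_decision <- function(result, true_state, strategy) {
  stopifnot(result %in% c("positive", "negative"))
  if (!true_state %in% colnames(strategy$decisions))
    stop("decision map does not cover state '", true_state, "'",
         call. = FALSE)
  action <- strategy$decisions[result, true_state]
  list(action = action, fee = strategy$test$fee,
       treated = action %in% .treat_actions)
}
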
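#' Exact expected cost and effect by cohort occupancy propagation
#'
#' Deterministic counterpart of [simulate_cohort()]: propagates the cohort
#' occupancy vector through the age-dependent transition matrices,
#' `o[t+1] = o[t] %*% P[t]`, accruing discounted expected rewards at every
#' cycle. Exact up to floating point, so it serves as an independent oracle
#' for the microsimulation.
#'
#' Screening is folded into composite transition rows in expectation: with
#' `k` test applications per cycle and per-application probability `p` of a
#' treatment-triggering result in a given state, the treated branch of the
#' transition function is mixed in with weight `1 - (1 - p)^k`, and expected
#' fees and action costs are accrued per occupied state. This is exact
#' because the microsimulation draws a single transition from exactly this
#' mixture.
#'
#' @inheritParams simulate_cohort
#' @param max_cycles Safety cap for unbounded horizons.
#' @param tol For unbounded horizons, stop once the occupancy mass outside
#'   zero-reward absorbing states falls below `tol`.
#' @return List with expected `cost` and `effect` (discounted), and the
#'   number of `cycles` propagated.
#' @export
solve_cohort_analytic <- function(spec, rewards, strategy = NULL,
                                  params = list(), discount_rate = 0.03,
                                  max_cycles = 100000, tol = 1e-13,
                                  validate = TRUE) {
  stopifnot(inherits(spec, "markov_model"), inherits(rewards, "reward_spec"))
  if (validate) {
    v <- validate_model(spec, params)
    if (length(v) > 0)
      stop("model validation failed:\n  ", paste(v, collapse = "\n  "),
           call. = FALSE)
  }
  ids <- spec$state_ids
  S <- length(ids)
  rw <- .reward_vectors(rewards, ids)
  absorbing_idx <- match(spec$absorbing, ids)
  terminal <- logical(S)
  terminal[absorbing_idx[rw$state_cost[absorbing_idx] == 0 &
                         rw$state_effect[absorbing_idx] == 0]] <- TRUE
  if (!is.finite(spec$max_age) && any(!terminal[absorbing_idx]))
    stop("reward-bearing absorbing states require a finite max_age",
         call. = FALSE)

  # expected screening accruals and per-state treatment probability
  p_pos <- if (!is.null(strategy)) .positive_prob(strategy$test, ids)
  act_cost <- stats::setNames(numeric(length(.actions)), .actions)
  if (!is.null(rewards$action_cost))
    act_cost[names(rewards$action_cost)] <- rewards$action_cost

  o <- spec$entry_state_distribution
  total_cost <- total_effect <- 0
  n_cycles <- if (is.finite(spec$max_age)) spec$max_age - spec$entry_age
              else Inf
  t <- 0
  while (t < n_cycles) {
    live_mass <- sum(o[!terminal])
    if (!is.finite(n_cycles) && live_mass < tol) break
    if (t >= max_cycles)
      stop("no convergence after ", max_cycles, " cycles", call. = FALSE)
    age <- spec$entry_age + t
    df <- 1 / (1 + discount_rate)^t

    p_treat <- numeric(S)
    screen_cost <- numeric(S)
    if (!is.null(strategy)) {
      k <- schedule_tests(strategy$schedule, t)
      if (k > 0) {
        a_pos <- strategy$decisions["positive", ids]
        a_neg <- strategy$decisions["negative", ids]
        p_app_treat <- p_pos * (a_pos %in% .treat_actions) +
          (1 - p_pos) * (a_neg %in% .treat_actions)
        p_treat <- 1 - (1 - p_app_treat)^k
        screen_cost <- k * (strategy$test$fee +
                            p_pos * act_cost[a_pos] +
                            (1 - p_pos) * act_cost[a_neg])
        screen_cost[terminal] <- 0   # the dead are not tested
        p_treat[terminal] <- 0
      }
    }

    total_cost <- total_cost + df * sum(o * (rw$state_cost + screen_cost))
    total_effect <- total_effect + df * sum(o * rw$state_effect)

    P <- .transition_matrix(spec, age, params, treated = FALSE)
    if (any(p_treat > 0)) {
      Pt <- .transition_matrix(spec, age, params, treated = TRUE)
      P <- (1 - p_treat) * P + p_treat * Pt
    }
    if (!is.null(rw$event_cost)) {
      ev <- rowSums(P * rw$event_cost)
      ev[terminal] <- 0
      total_cost <- total_cost + df * sum(o * ev)
    }
    if (!is.null(rw$event_effect)) {
      ev <- rowSums(P * rw$event_effect)
      ev[terminal] <- 0
      total_effect <- total_effect + df * sum(o * ev)
    }
    o <- as.vector(o %*% P)
    names(o) <- ids
    t <- t + 1
  }
  list(cost = total_cost, effect = total_effect, cycles = t)
}
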
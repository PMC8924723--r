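# Microsimulation engine.
#
# All randomness flows through three dedicated uniform streams (entry state,
# test classification, state transition), each derived from the master seed.
# Per cycle, each stream is consumed in fixed-length blocks of n regardless
# of how many individuals are still in the model, so two arms simulated with
# the same seed see identical per-individual uniforms (common random
# numbers): arm differences reflect the strategies, not sampling noise.

# a resumable uniform stream with its own RNG state
.make_stream <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  env$state <- get(".Random.seed", envir = globalenv())
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  function(n) {
    outer <- get0(".Random.seed", envir = globalenv())
    assign(".Random.seed", env$state, envir = globalenv())
    u <- stats::runif(n)
    env$state <- get(".Random.seed", envir = globalenv())
    if (is.null(outer)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", outer, envir = globalenv())
    }
    u
  }
}

# inverse-CDF draw: one uniform per transition, identical consumption across
# strategies so that common random numbers stay aligned
.draw_states <- function(u, cum) {
  findInterval(u, cum, rightmost.closed = TRUE) + 1L
}

#' Simulate a cohort of independent individuals through a screening model
#'
#' Runs `n` individual trajectories through a [markov_model()]. Each cycle
#' applies, in order: the screening tests due that cycle (fees, decision
#' actions and their costs, possible routing to the treated transition
#' branch), then per-state reward accrual, then one state transition with
#' any per-transition event rewards. Costs and effects are discounted by
#' whole years since entry (cycle 0 undiscounted). A trajectory ends when it
#' enters an absorbing state with zero rewards, or when age reaches
#' `spec$max_age`.
#'
#' Two calls with the same `seed` are bit-identical; two strategies run with
#' the same `seed` share per-individual random streams (common random
#' numbers).
#'
#' @param spec A [markov_model()].
#' @param rewards A [reward_spec()].
#' @param strategy A [screening_strategy()], or `NULL` for a screening-free
#'   run.
#' @param params Parameter list passed to the transition function.
#' @param n Number of individuals (>= 1).
#' @param seed Integer master seed.
#' @param discount_rate Annual discount rate applied to both costs and
#'   effects (both are discounted by default; set 0 to disable).
#' @param record_trajectories If `TRUE`, keep per-cycle records (one row per
#'   individual-cycle, undiscounted accruals) — intended for small `n`.
#' @param validate If `TRUE` (default), run [validate_model()] first and
#'   stop on violations.
#' @return An object of class `simulation_result`: list with `n`,
#'   `mean_cost`, `mean_effect`, per-individual `cost` and `effect` vectors,
#'   `seed`, and (optionally) `trajectories`, a data frame of per-cycle
#'   records.
#' @export
simulate_cohort <- function(spec, rewards, strategy = NULL, params = list(),
                            n, seed, discount_rate = 0.03,
                            record_trajectories = FALSE, validate = TRUE) {
  stopifnot(inherits(spec, "markov_model"), inherits(rewards, "reward_spec"))
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
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
  # terminal = absorbing with nothing left to accrue: simulation may stop
  terminal_idx <- absorbing_idx[rw$state_cost[absorbing_idx] == 0 &
                                rw$state_effect[absorbing_idx] == 0]
  if (!is.finite(spec$max_age) && length(setdiff(absorbing_idx, terminal_idx)))
    stop("reward-bearing absorbing states require a finite max_age",
         call. = FALSE)

  set.seed(seed)
  ss <- sample.int(.Machine$integer.max - 1L, 3L)
  u_entry <- .make_stream(ss[1])
  u_class <- .make_stream(ss[2])
  u_trans <- .make_stream(ss[3])

  ecum <- cumsum(spec$entry_state_distribution)
  ecum[length(ecum)] <- 1
  st <- .draw_states(u_entry(n), ecum)
  cost <- effect <- numeric(n)
  alive <- !(st %in% terminal_idx)

  p_pos <- if (!is.null(strategy)) .positive_prob(strategy$test, ids)
  act_cost <- stats::setNames(numeric(length(.actions)), .actions)
  if (!is.null(rewards$action_cost))
    act_cost[names(rewards$action_cost)] <- rewards$action_cost
  treat_lookup <- if (!is.null(strategy))
    matrix(strategy$decisions %in% .treat_actions, nrow = 2,
           dimnames = dimnames(strategy$decisions))
  action_cost_lookup <- if (!is.null(strategy))
    matrix(act_cost[strategy$decisions], nrow = 2,
           dimnames = dimnames(strategy$decisions))

  n_cycles <- if (is.finite(spec$max_age)) spec$max_age - spec$entry_age
              else Inf
  rec <- if (record_trajectories) vector("list", 64)
  nrec <- 0L
  if (record_trajectories && any(!alive)) {
    # individuals entering a terminal state: a single record, nothing accrued
    dead <- which(!alive)
    nrec <- 1L
    rec[[1]] <- data.frame(individual = dead, cycle = 0L,
                           age = spec$entry_age, state = ids[st[dead]],
                           cost = 0, effect = 0)
  }
  t <- 0L
  while (any(alive) && t < n_cycles) {
    if (t >= 10000L)
      stop("horizon not reached after 10000 cycles; ",
           "set a finite max_age or make an absorbing state reachable",
           call. = FALSE)
    age <- spec$entry_age + t
    df <- 1 / (1 + discount_rate)^t
    ia <- which(alive)
    sa <- st[ia]
    treated <- logical(length(ia))
    cyc_cost <- numeric(length(ia))   # undiscounted, for trajectory records

    if (!is.null(strategy)) {
      k <- schedule_tests(strategy$schedule, t)
      if (k > 0) {
        for (a in seq_len(k)) {
          u <- u_class(n)[ia]
          row <- ifelse(u < p_pos[sa], 1L, 2L)   # 1 = positive, 2 = negative
          idx2 <- cbind(row, sa)
          cyc_cost <- cyc_cost + strategy$test$fee + action_cost_lookup[idx2]
          treated <- treated | treat_lookup[idx2]
        }
      }
    }

    cyc_cost <- cyc_cost + rw$state_cost[sa]
    cyc_effect <- rw$state_effect[sa]

    Pu <- .transition_matrix(spec, age, params, treated = FALSE)
    cum_u <- t(apply(Pu, 1, cumsum)); cum_u[, S] <- 1
    if (any(treated)) {
      Pt <- .transition_matrix(spec, age, params, treated = TRUE)
      cum_t <- t(apply(Pt, 1, cumsum)); cum_t[, S] <- 1
    }
    u <- u_trans(n)[ia]
    nxt <- integer(length(ia))
    for (s in unique(sa)) {
      for (tr in c(FALSE, TRUE)) {
        sel <- sa == s & treated == tr
        if (!any(sel)) next
        cum <- if (tr) cum_t[s, ] else cum_u[s, ]
        nxt[sel] <- .draw_states(u[sel], cum)
      }
    }
    if (!is.null(rw$event_cost))
      cyc_cost <- cyc_cost + rw$event_cost[cbind(sa, nxt)]
    if (!is.null(rw$event_effect))
      cyc_effect <- cyc_effect + rw$event_effect[cbind(sa, nxt)]

    cost[ia] <- cost[ia] + df * cyc_cost
    effect[ia] <- effect[ia] + df * cyc_effect
    if (record_trajectories) {
      nrec <- nrec + 1L
      if (nrec > length(rec)) rec <- c(rec, vector("list", length(rec)))
      rec[[nrec]] <- data.frame(individual = ia, cycle = t, age = age,
                                state = ids[sa], cost = cyc_cost,
                                effect = cyc_effect)
    }
    st[ia] <- nxt
    alive[ia[nxt %in% terminal_idx]] <- FALSE
    t <- t + 1L
  }

  out <- list(n = n, mean_cost = mean(cost), mean_effect = mean(effect),
              cost = cost, effect = effect, seed = seed,
              discount_rate = discount_rate,
              currency = rewards$currency, effect_unit = rewards$effect_unit)
  if (record_trajectories) {
    tr <- do.call(rbind, rec[seq_len(nrec)])
    tr <- tr[order(tr$individual, tr$cycle), , drop = FALSE]
    rownames(tr) <- NULL
    out$trajectories <- tr
  }
  structure(out, class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result> n =", x$n, " seed =", x$seed, "\n")
  cat(sprintf("  mean cost:   %.4f %s\n", x$mean_cost, x$currency))
  cat(sprintf("  mean effect: %.4f %s\n", x$mean_effect, x$effect_unit))
  invisible(x)
}

#' Simulate a single individual trajectory
#'
#' Convenience wrapper around [simulate_cohort()] with `n = 1` and
#' trajectory recording on: returns the per-cycle record of one individual
#' (age, state, undiscounted cost and effect accruals) together with the
#' discounted totals.
#'
#' @inheritParams simulate_cohort
#' @return A list of class `trajectory`: `records` (data frame, one row per
#'   cycle), `total_cost`, `total_effect` (discounted), `seed`.
#' @export
simulate_individual <- function(spec, rewards, strategy = NULL,
                                params = list(), seed,
                                discount_rate = 0.03, validate = TRUE) {
  res <- simulate_cohort(spec, rewards, strategy, params, n = 1, seed = seed,
                         discount_rate = discount_rate,
                         record_trajectories = TRUE, validate = validate)
  structure(list(records = res$trajectories,
                 total_cost = res$cost[1], total_effect = res$effect[1],
                 seed = seed),
            class = "trajectory")
}
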
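# One-way deterministic sensitivity analysis and threshold detection.

#' One-way parameter sweep with common random numbers
#'
#' Re-evaluates the two-arm comparison on a grid of values of a single
#' parameter, holding everything else (including the random streams) fixed,
#' so differences along the grid are attributable to the parameter alone.
#' The parameter is any entry of the model's parameter list; by convention
#' `"fee"` is the AI per-use fee and `"discount"` the annual discount rate,
#' the two sweeps of primary interest (the discount grid spans 0-10%).
#'
#' @param model A [use_case_model()]-like object (`$build`, `$params`).
#' @param parameter Name of the parameter to vary.
#' @param grid Non-empty numeric grid of values.
#' @param n Individuals per evaluation.
#' @param seed Seed shared by all evaluations and both arms.
#' @return A tibble of class `sweep_table` with columns `value`, `cost_ai`,
#'   `effect_ai`, `cost_std`, `effect_std`, `delta_cost`, `delta_effect`,
#'   `icer`, `flag`, carrying the evaluator as an attribute so
#'   [find_threshold()] can refine crossings by bisection.
#' @export
one_way_sweep <- function(model, parameter, grid, n = 1000, seed) {
  stopifnot(length(grid) >= 1, is.numeric(grid))
  if (!parameter %in% c(names(model$params), "discount"))
    stop("unknown parameter '", parameter, "'", call. = FALSE)
  grid <- sort(grid)
  eval_point <- function(value) {
    pars <- model$params
    pars[[parameter]] <- value
    b <- model$build(pars)
    dr <- pars$discount %||% 0.03
    ai <- simulate_cohort(b$spec, b$rewards, b$arms$ai, pars, n = n,
                          seed = seed, discount_rate = dr, validate = FALSE)
    std <- simulate_cohort(b$spec, b$rewards, b$arms$standard, pars, n = n,
                           seed = seed, discount_rate = dr, validate = FALSE)
    dc <- ai$mean_cost - std$mean_cost
    de <- ai$mean_effect - std$mean_effect
    ic <- icer(dc, de)
    tibble::tibble(value = value,
                   cost_ai = ai$mean_cost, effect_ai = ai$mean_effect,
                   cost_std = std$mean_cost, effect_std = std$mean_effect,
                   delta_cost = dc, delta_effect = de,
                   icer = ic$ratio, flag = ic$flag)
  }
  out <- do.call(rbind, lapply(grid, eval_point))
  attr(out, "evaluator") <- eval_point
  attr(out, "parameter") <- parameter
  class(out) <- c("sweep_table", class(out))
  out
}

#' Detect the parameter value where dominance flips
#'
#' Scans a sorted sweep table for intervals where the dominance flag
#' changes and refines each crossing by bisection on the same deterministic
#' (fixed-seed) evaluation, to a tolerance in grid units. A change in
#' dominance classification (e.g. the AI arm ceasing to be dominant as its
#' fee rises) is the criterion.
#'
#' @param sweep A `sweep_table` from [one_way_sweep()], sorted by `value`.
#' @param tol Bisection tolerance on the parameter axis (default 0.01).
#' @return The crossing value (numeric), `NULL` if the flag never changes,
#'   or all crossing values with a warning if the flip is non-monotone.
#' @export
find_threshold <- function(sweep, tol = 0.01) {
  stopifnot(inherits(sweep, "sweep_table"))
  eval_point <- attr(sweep, "evaluator")
  flags <- sweep$flag
  vals <- sweep$value
  flips <- which(flags[-1] != flags[-length(flags)])
  if (length(flips) == 0) return(NULL)
  refine <- function(i) {
    lo <- vals[i]; hi <- vals[i + 1]
    flag_lo <- flags[i]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (eval_point(mid)$flag == flag_lo) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  crossings <- vapply(flips, refine, numeric(1))
  if (length(crossings) > 1)
    warning("non-monotone dominance flips: returning all ",
            length(crossings), " crossings", call. = FALSE)
  if (length(crossings) == 1) crossings[[1]] else crossings
}
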
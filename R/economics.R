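#' Incremental cost-effectiveness ratio with dominance flag
#'
#' `delta_cost / delta_effect` for the comparison of an intervention against
#' a comparator, together with a dominance flag, because a bare (especially
#' negative) ratio is ambiguous: `"dominant"` when the intervention is
#' cheaper and more effective, `"dominated"` when costlier and less
#' effective, `"undefined"` when the effect difference is zero, `"none"`
#' otherwise (a genuine trade-off).
#'
#' @param delta_cost Incremental cost (intervention minus comparator).
#' @param delta_effect Incremental effect.
#' @return List with `ratio` (`NA` when undefined) and `flag`.
#' @export
icer <- function(delta_cost, delta_effect) {
  stopifnot(is.finite(delta_cost), is.finite(delta_effect))
  flag <- if (delta_effect == 0) "undefined"
          else if (delta_cost < 0 && delta_effect > 0) "dominant"
          else if (delta_cost > 0 && delta_effect < 0) "dominated"
          else "none"
  ratio <- if (delta_effect == 0) NA_real_ else delta_cost / delta_effect
  list(ratio = ratio, flag = flag)
}

#' Net monetary benefit
#'
#' `WTP x delta_effect - delta_cost`: positive means the intervention is
#' cost-effective for a payer with willingness-to-pay ceiling `wtp` per
#' effect unit.
#'
#' @param wtp Willingness-to-pay per effect unit (>= 0; vectorised).
#' @param delta_effect,delta_cost Incremental effect and cost (vectorised).
#' @return Net monetary benefit, in money units.
#' @export
net_benefit <- function(wtp, delta_effect, delta_cost) {
  stopifnot(all(wtp >= 0))
  wtp * delta_effect - delta_cost
}

#' Paired cost-effect draws for two arms
#'
#' The substrate of all probabilistic economics: one row per probabilistic
#' sensitivity analysis replicate, holding each arm's mean cost and effect.
#'
#' @param cost_ai,effect_ai,cost_std,effect_std Equal-length numeric vectors
#'   (length >= 1).
#' @param currency,effect_unit Tags carried along for labelling.
#' @return A tibble of class `ce_draws` with columns `replicate`, `cost_ai`,
#'   `effect_ai`, `cost_std`, `effect_std`.
#' @export
ce_draws <- function(cost_ai, effect_ai, cost_std, effect_std,
                     currency = "EUR", effect_unit = "QALY") {
  len <- length(cost_ai)
  stopifnot(len >= 1, length(effect_ai) == len, length(cost_std) == len,
            length(effect_std) == len)
  out <- tibble::tibble(replicate = seq_len(len),
                        cost_ai = cost_ai, effect_ai = effect_ai,
                        cost_std = cost_std, effect_std = effect_std)
  attr(out, "currency") <- currency
  attr(out, "effect_unit") <- effect_unit
  class(out) <- c("ce_draws", class(out))
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of replicates in which
#' the intervention arm has positive net benefit against the comparator
#' (replicates with net benefit exactly zero count one half). Equivalent to
#' brute-force counting over draws.
#'
#' @param draws A [ce_draws()] object (or data frame with its columns).
#' @param wtp_grid Non-empty vector of non-negative WTP values.
#' @return A tibble of class `ceac_curve` with columns `wtp` and
#'   `p_cost_effective`.
#' @export
ceac <- function(draws, wtp_grid) {
  if (is.null(draws) || nrow(draws) == 0)
    stop("draws must contain at least one replicate", call. = FALSE)
  stopifnot(length(wtp_grid) >= 1, all(wtp_grid >= 0))
  de <- draws$effect_ai - draws$effect_std
  dc <- draws$cost_ai - draws$cost_std
  p <- vapply(wtp_grid, function(w) {
    nb <- net_benefit(w, de, dc)
    mean(nb > 0) + 0.5 * mean(nb == 0)
  }, numeric(1))
  out <- tibble::tibble(wtp = wtp_grid, p_cost_effective = p)
  class(out) <- c("ceac_curve", class(out))
  out
}

#' 2020 purchasing power parity rates
#'
#' OECD 2020 purchasing power parities used to express local-currency costs
#' in US dollars: 0.746 EUR and 2.362 BRL per 1 USD.
#'
#' @return Named vector of local-currency-per-USD rates, with a
#'   `reference_year` attribute.
#' @export
ppp_rates <- function() {
  structure(c(EUR = 0.746, BRL = 2.362, USD = 1),
            reference_year = 2020)
}

#' Convert a local-currency amount to USD at a PPP rate
#'
#' `amount / rate`, full precision; rounding happens only at presentation
#' (see [present_money()]).
#'
#' @param amount Amount in local currency (vectorised).
#' @param rate Local currency units per USD (> 0). Defaults can be looked up
#'   with [ppp_rates()].
#' @return The USD amount.
#' @export
ppp_convert <- function(amount, rate) {
  stopifnot(is.numeric(rate), all(rate > 0))
  amount / rate
}

#' Round money for presentation
#'
#' Half-away-from-zero rounding to a fixed number of decimals, the
#' convention used in all printed tables; internal arithmetic is never
#' rounded.
#'
#' @param x Amount (vectorised).
#' @param digits Decimal places (default 2).
#' @return Rounded amount.
#' @export
present_money <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' WHO cost-effectiveness ceiling
#'
#' The World Health Organization rule of thumb: an intervention is
#' considered cost-effective if it costs up to 3 times the GDP per capita
#' per effect unit gained.
#'
#' @param gdp_per_capita GDP per capita (> 0), any currency.
#' @return `3 * gdp_per_capita`, same currency.
#' @export
who_threshold <- function(gdp_per_capita) {
  stopifnot(all(gdp_per_capita > 0))
  3 * gdp_per_capita
}
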
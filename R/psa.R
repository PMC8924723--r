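# Parameter uncertainty: distribution fitting, sampling, and the PSA loop.

#' Describe the uncertainty distribution of one model parameter
#'
#' Families follow standard health-economics practice: beta for
#' probabilities and utilities (bounded to \[0, 1\]), gamma for costs
#' (positive), uniform where only a range is defensible, and `fixed` for
#' parameters without uncertainty. Beta and gamma distributions are
#' parameterised by the reported mean and 95% CI: the two distribution
#' parameters are fitted so the 2.5% and 97.5% quantiles match the CI
#' bounds (the mean must lie inside the CI and is validated, not forced).
#'
#' @param name Parameter name (must exist in the model's parameter list).
#' @param family `"beta"`, `"gamma"`, `"uniform"` or `"fixed"`.
#' @param mean Reported central value (required for beta/gamma/fixed).
#' @param ci Length-2 vector, the reported 95% CI (beta/gamma) or the range
#'   (uniform).
#' @param bounds Optional hard bounds the sampled value must satisfy;
#'   defaults to \[0, 1\] for beta, (0, Inf) for gamma.
#' @return An object of class `param_dist`.
#' @export
param_dist <- function(name, family = c("beta", "gamma", "uniform", "fixed"),
                       mean = NULL, ci = NULL, bounds = NULL) {
  family <- match.arg(family)
  if (family == "fixed") {
    if (is.null(mean)) stop("fixed distribution for '", name,
                            "' needs a mean value", call. = FALSE)
    return(structure(list(name = name, family = family, mean = mean,
                          ci = c(mean, mean), bounds = bounds,
                          fit = NULL), class = "param_dist"))
  }
  if (family == "uniform") {
    stopifnot(length(ci) == 2)
    if (ci[1] >= ci[2]) stop("uniform bounds for '", name,
                             "' must be ordered", call. = FALSE)
    if (is.null(mean)) mean <- base::mean(ci)
    return(structure(list(name = name, family = family, mean = mean,
                          ci = ci, bounds = bounds %||% ci, fit = NULL),
                     class = "param_dist"))
  }
  stopifnot(length(ci) == 2, ci[1] < ci[2], !is.null(mean))
  if (mean <= ci[1] || mean >= ci[2])
    stop("parameter '", name, "': mean ", mean,
         " lies outside its 95% CI (", ci[1], ", ", ci[2], ")",
         call. = FALSE)
  fit <- switch(family,
                beta = .fit_beta_quantiles(mean, ci[1], ci[2]),
                gamma = .fit_gamma_quantiles(mean, ci[1], ci[2]))
  bounds <- bounds %||% switch(family, beta = c(0, 1), gamma = c(0, Inf))
  structure(list(name = name, family = family, mean = mean, ci = ci,
                 bounds = bounds, fit = fit), class = "param_dist")
}

# fit (shape1, shape2) so qbeta(.025/.975) match the CI; moment-matched start
.fit_beta_quantiles <- function(mean, lo, hi) {
  stopifnot(lo > 0, hi < 1, mean > 0, mean < 1)
  sd0 <- (hi - lo) / (2 * stats::qnorm(0.975))
  k <- max(mean * (1 - mean) / sd0^2 - 1, 0.1)
  init <- log(c(mean * k, (1 - mean) * k))
  obj <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    (stats::qbeta(0.025, a, b) - lo)^2 + (stats::qbeta(0.975, a, b) - hi)^2
  }
  fit <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 10000))
  list(shape1 = exp(fit$par[1]), shape2 = exp(fit$par[2]),
       quantile_error = sqrt(fit$value))
}

# fit (shape, rate) so qgamma(.025/.975) match the CI
.fit_gamma_quantiles <- function(mean, lo, hi) {
  stopifnot(lo > 0, mean > 0)
  sd0 <- (hi - lo) / (2 * stats::qnorm(0.975))
  shape0 <- (mean / sd0)^2
  init <- log(c(shape0, shape0 / mean))
  obj <- function(par) {
    sh <- exp(par[1]); rt <- exp(par[2])
    (stats::qgamma(0.025, sh, rt) - lo)^2 +
      (stats::qgamma(0.975, sh, rt) - hi)^2
  }
  fit <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 10000))
  list(shape = exp(fit$par[1]), rate = exp(fit$par[2]),
       quantile_error = sqrt(fit$value))
}

# one draw from a fitted distribution, respecting hard bounds by rejection
.sample_dist <- function(d) {
  draw <- function() switch(
    d$family,
    fixed = d$mean,
    uniform = stats::runif(1, d$ci[1], d$ci[2]),
    beta = stats::rbeta(1, d$fit$shape1, d$fit$shape2),
    gamma = stats::rgamma(1, d$fit$shape, d$fit$rate))
  x <- draw()
  if (!is.null(d$bounds)) {
    tries <- 0
    while (x < d$bounds[1] || x > d$bounds[2]) {
      x <- draw()
      tries <- tries + 1
      if (tries > 1000)
        stop("parameter '", d$name,
             "': cannot sample within bounds", call. = FALSE)
    }
  }
  x
}

#' Draw one concrete parameter set from uncertainty distributions
#'
#' @param distributions List of [param_dist()] objects.
#' @return Named list of sampled values, one per distribution; `fixed`
#'   entries pass through unchanged. Uses the current RNG state, so seed
#'   upstream for reproducibility.
#' @export
sample_parameters <- function(distributions) {
  stopifnot(all(vapply(distributions, inherits, logical(1), "param_dist")))
  vals <- lapply(distributions, .sample_dist)
  stats::setNames(vals, vapply(distributions, `[[`, character(1), "name"))
}

#' Empirical percentile confidence interval
#'
#' 2.5% and 97.5% percentiles (by default) of a sample, with linear
#' interpolation between order statistics.
#'
#' @param values Numeric vector, length >= 2.
#' @param lo,hi Percentile levels.
#' @return Length-2 numeric vector `(lower, upper)`.
#' @export
percentile_ci <- function(values, lo = 0.025, hi = 0.975) {
  if (length(values) < 2)
    stop("percentile_ci needs at least 2 values", call. = FALSE)
  unname(stats::quantile(values, c(lo, hi), type = 7, names = FALSE))
}

#' Probabilistic sensitivity analysis over a use-case model
#'
#' The full PSA loop: for each of `n_psa` replicates, draws one parameter
#' set from the uncertainty distributions, rebuilds the model, and runs both
#' arms through the microsimulation with common random numbers (both arms of
#' a replicate share the same per-individual streams). Produces the paired
#' cost-effect draws plus per-arm means, percentile intervals, and the ICER
#' of the mean differences.
#'
#' @param model A [use_case_model()] (or any object with `$build(params)`
#'   returning `list(spec, rewards, arms)` and `$params`).
#' @param distributions List of [param_dist()] objects over entries of the
#'   model's parameter list (may be empty for a fixed-parameter run).
#' @param n_psa Number of parameter replicates (default 1000).
#' @param n_individuals Individuals (or teeth) per microsimulation
#'   (default 1000).
#' @param seed Master seed; the whole PSA is reproducible from it.
#' @param discount_rate Annual discount rate for costs and effects; default
#'   taken from the model's parameters (falling back to 3%).
#' @return An object of class `psa_result`: list with `draws` (a
#'   [ce_draws()] tibble), `summary` (per-arm mean and 95% percentile CI of
#'   cost and effect over replicate means), `icer` (of mean differences),
#'   `n_psa`, `n_individuals`, `seed`.
#' @export
run_psa <- function(model, distributions = list(), n_psa = 1000,
                    n_individuals = 1000, seed, discount_rate = NULL) {
  stopifnot(n_psa >= 1, n_individuals >= 1)
  discount_rate <- discount_rate %||% (model$params$discount %||% 0.03)
  set.seed(seed)
  param_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  sim_seeds <- sample.int(.Machine$integer.max - 1L, n_psa)

  # validate once with base parameters; replicates skip revalidation
  base <- model$build(model$params)
  v <- validate_model(base$spec, model$params)
  if (length(v) > 0)
    stop("model validation failed:\n  ", paste(v, collapse = "\n  "),
         call. = FALSE)

  set.seed(param_seed)
  sampled <- lapply(seq_len(n_psa), function(k) sample_parameters(distributions))

  cost_ai <- effect_ai <- cost_std <- effect_std <- numeric(n_psa)
  for (k in seq_len(n_psa)) {
    pars <- utils::modifyList(model$params, sampled[[k]])
    b <- model$build(pars)
    ai <- simulate_cohort(b$spec, b$rewards, b$arms$ai, pars,
                          n = n_individuals, seed = sim_seeds[k],
                          discount_rate = discount_rate, validate = FALSE)
    std <- simulate_cohort(b$spec, b$rewards, b$arms$standard, pars,
                           n = n_individuals, seed = sim_seeds[k],
                           discount_rate = discount_rate, validate = FALSE)
    cost_ai[k] <- ai$mean_cost;   effect_ai[k] <- ai$mean_effect
    cost_std[k] <- std$mean_cost; effect_std[k] <- std$mean_effect
  }
  draws <- ce_draws(cost_ai, effect_ai, cost_std, effect_std,
                    currency = base$rewards$currency,
                    effect_unit = base$rewards$effect_unit)
  summarise_arm <- function(x) {
    ci <- if (n_psa >= 2) percentile_ci(x) else c(NA_real_, NA_real_)
    c(mean = mean(x), lower = ci[1], upper = ci[2])
  }
  summary <- tibble::tibble(
    arm = rep(c("ai", "standard"), each = 2),
    quantity = rep(c("cost", "effect"), 2),
    mean = c(mean(cost_ai), mean(effect_ai), mean(cost_std),
             mean(effect_std)),
    lower = c(summarise_arm(cost_ai)[2], summarise_arm(effect_ai)[2],
              summarise_arm(cost_std)[2], summarise_arm(effect_std)[2]),
    upper = c(summarise_arm(cost_ai)[3], summarise_arm(effect_ai)[3],
              summarise_arm(cost_std)[3], summarise_arm(effect_std)[3]))
  ic <- icer(mean(cost_ai) - mean(cost_std),
             mean(effect_ai) - mean(effect_std))
  structure(list(draws = draws, summary = summary, icer = ic,
                 n_psa = n_psa, n_individuals = n_individuals, seed = seed,
                 discount_rate = discount_rate, label = model$label),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result>", x$label %||% "", " n_psa =", x$n_psa,
      " n_individuals =", x$n_individuals, " seed =", x$seed, "\n")
  print(x$summary)
  cat(sprintf("  ICER (of means): %s  [%s]\n",
              ifelse(is.na(x$icer$ratio), "undefined",
                     format(x$icer$ratio, digits = 6)), x$icer$flag))
  invisible(x)
}
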
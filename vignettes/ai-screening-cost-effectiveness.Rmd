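---
title: "Modelling the cost-effectiveness of AI-assisted diagnostic screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-effectiveness of AI-assisted diagnostic screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markovscreen)
```

## The question the package models

When an AI decision-support system reads the same images a clinician reads
— skin photographs, bitewing radiographs, fundus photographs — it changes
two things: the sensitivity/specificity of detection, and the cost of every
test application (a per-use fee). Whether that trade is worth it is a
health-economic question, not a machine-learning one: a more sensitive test
finds disease earlier (cheaper, more effective treatment) but a less
specific one triggers work-ups and overtreatment, and the fee is paid at
every screen over a lifetime horizon.

`markovscreen` answers this with the standard machinery of model-based
economic evaluation: a discrete-time Markov microsimulation of individuals
through health states, an imperfect-test screening layer on top, and the
incremental cost-effectiveness stack (ICER, net monetary benefit,
acceptability curves, probabilistic and one-way sensitivity analysis,
purchasing-power-parity conversion). Three configurable model families are
bundled — melanoma detection (per person, QALYs, USD), proximal caries
detection (per tooth, tooth-retention-years, EUR) and diabetic retinopathy
grading (per person, utility-weighted QALYs, BRL) — and the engine accepts
any well-formed model, so the bundled state lists are defaults, not limits.

## The simulation model

Time advances in annual cycles from a use-case-specific entry age (50 for
melanoma screening of the general population, 12 for a freshly erupted
permanent tooth, 40 for a diabetic cohort) to a horizon age. Each cycle
applies, in this order:

1. **Screening.** `schedule_tests()` says how many test applications fall
   in the cycle (tests sit at times $0, 1/s, 2/s, \dots$ from entry, so a
   twice-yearly schedule gives 2 per cycle and a biennial one alternates
   1, 0, 1, 0). Each application returns positive with probability equal
   to the test's sensitivity in diseased states and $1-\text{specificity}$
   elsewhere; the decision map turns (result, state) into an action. Treat
   actions route the individual onto the *treated branch* of the
   transition function for this cycle; `refer`/`monitor` may carry a
   one-time work-up cost; every application accrues the test's fee.
2. **Reward accrual.** The occupied state's per-cycle cost and effect.
3. **Transition.** One draw from the (age- and treatment-dependent)
   transition row, with any per-transition event rewards (excision,
   restoration, extraction, laser treatment, end-of-life care).

Costs and effects are discounted by whole years since entry,
$x/(1+r)^t$, with cycle 0 undiscounted and $r = 3\%$ by default (swept
0–10% in sensitivity analysis). Both costs and effects are discounted by
default; pass `discount_rate = 0` to disable. There is no half-cycle
correction: rewards belong to the state occupied at cycle start. That
choice keeps the analytic solver exact and is common microsimulation
practice; the alternative (half-cycle weights) shifts levels slightly but
not arm differences, which is what all conclusions rest on.

Background mortality is composed with disease dynamics as a competing
risk: the disease transition is taken first, then an age-indexed
background death probability applies to survivors
(`add_background_mortality()`), with disease-specific death states exempt.
Absorbing states with zero rewards (death, tooth loss) end a trajectory;
absorbing states that still accrue — established blindness keeps its
utility until background death — are carried to the horizon.

### Common random numbers

All randomness flows through three dedicated uniform streams (entry
states, test classifications, transitions) derived from one master seed,
consumed in fixed blocks of $n$ per cycle. Two arms simulated with the
same seed therefore see identical per-individual uniforms, so incremental
quantities are differences between matched trajectories, not between
independent samples: with identical tests and fees the two arms coincide
*exactly*, and a fee change moves costs without touching a single effect
value. The suite asserts both properties literally.

### The analytic oracle

`solve_cohort_analytic()` propagates the cohort occupancy vector,
$o_{t+1} = o_t P_t$, accruing expected discounted rewards — exact up to
floating point. Screening folds into composite rows in expectation: with
$k$ applications and per-application treatment-trigger probability $p$,
the treated branch mixes in with weight $1-(1-p)^k$, and expected fees and
action costs accrue per occupied state. Because the microsimulation draws
its single transition from exactly that mixture, the two paths estimate
the same quantity by entirely different code, which is what makes the
solver a genuine oracle: the tests require agreement within 3 Monte Carlo
standard errors on batches of generated scenarios, and agreement to
`1e-9` with hand-derived geometric closed forms.

## The economics layer

For arm means $(\bar c_{AI}, \bar e_{AI})$ and
$(\bar c_{std}, \bar e_{std})$:

* `icer()` returns $\Delta c/\Delta e$ **with a dominance flag** —
  `dominant` (cheaper, more effective), `dominated`, `undefined`
  ($\Delta e = 0$) — because a bare negative ratio cannot distinguish a
  cost-saving improvement from a costlier harm.
* `net_benefit()` is $\lambda\,\Delta e-\Delta c$ at willingness-to-pay
  $\lambda$; `ceac()` counts, per $\lambda$, the fraction of PSA
  replicates with positive net benefit. Replicates with net benefit
  exactly zero count one half: a measure-zero convention for continuous
  draws that keeps degenerate test cases deterministic.
* `ppp_convert()` divides by the 2020 OECD purchasing power parities
  (0.746 EUR, 2.362 BRL per USD); `who_threshold()` is the 3×-GDP-per-
  capita ceiling. Internal arithmetic is never rounded; presentation uses
  half-away-from-zero to a stated number of decimals (`present_money()`),
  one convention throughout rather than the mixed rounding/truncation
  found in printed tables.

## Parameter uncertainty

`param_dist()` fits beta distributions to probabilities and utilities and
gamma to costs, given the reported mean and 95% CI; caries lesion
initiation/progression uses uniform ranges. With a two-parameter family
the mean and both CI bounds cannot all be matched exactly, so the two
distribution parameters are fitted to the 2.5% and 97.5% quantiles
(Nelder–Mead on log-parameters from a moment-matched start, quantile
errors below $10^{-6}$ in the bundled sets) and the mean is validated to
lie inside the CI — a mean outside its CI is rejected by name. The
round-trip property (sampled percentiles recover the stated CI within
0.01) is asserted at 100,000 draws.

`run_psa()` interprets "replicated microsimulation" as $n_{psa}$
parameter draws × $n_{ind}$ individuals per draw, both configurable,
defaulting to 1000 × 1000. Percentile intervals (2.5%, 97.5%) are taken
over PSA replicate means with linear interpolation between order
statistics. One-way sweeps (`one_way_sweep()`) re-run both arms on a grid
with common random numbers; `find_threshold()` locates dominance flips
and refines them by bisection to 0.01 grid units, returning all crossings
with a warning if the flip is non-monotone.

## The synthetic parameter generator

The three source models' transition tables are not part of this artifact,
so `generate_default_params()` emits complete, internally consistent,
clearly flagged synthetic sets. Only externally anchored values are fixed:
the 8-unit per-use fee, 3% discounting, entry ages 50/12/40, schedules
1/yr, 2/yr and 0.5/yr, and the PPP rates. Everything else — incidences,
progression and failure probabilities, stage utilities, tariffs, Gompertz
background mortality (`generate_life_table()`, hazard doubling roughly
every 8 years, certain death by 110, diabetic and blindness hazard
multipliers in the retinopathy model) — is an invented plausible
magnitude with a seeded jitter and a symmetric synthetic CI.

Consequences to keep in mind:

* Passing tests show the *machinery* is right (oracle equivalence,
  determinism, monotonicities, exact counting), not that any particular
  published cost or ICER is reproduced. Under the synthetic defaults the
  dentistry AI arm, for example, is *more* expensive than standard care,
  because an 8 EUR fee charged per application, twice yearly over a
  ~70-year tooth horizon, dwarfs plausible restorative savings.
* `generate_known_truth_scenario()` emits deliberately simple instances —
  two-state survival chains, a tooth chain with identical perfect-test
  arms, a three-state morbidity chain — together with closed-form
  reference values (geometric and two-stage geometric sums), and these
  references are required to match the analytic solver to $10^{-9}$.
* `build_fee_threshold_toy()` is the deterministic break-even instance: 4
  lifetime tests against 64 units of avoidable late-treatment cost, so
  dominance flips at fee $= 64/4 = 16$ exactly, which the sweep-plus-
  bisection machinery must find within 0.01.

Real data differ in ways the generator does not emulate: correlated
parameters (the PSA samples independently), non-stationary incidence,
adherence and referral behaviour, and reader–AI interaction effects
(perfect congruence with the test result is assumed, as a base case).

## Numerical and design choices

* Transition draws invert the row CDF with a single uniform; the last
  cumulative entry is forced to 1 so validated rows (sum within $10^{-9}$)
  never leak probability.
* `validate_model()` returns violations as data (state, age, rule), not
  exceptions; simulation entry points validate once and PSA replicates
  skip re-validation for speed.
* Unbounded horizons are allowed when every path reaches a zero-reward
  absorbing state; the analytic solver iterates until live occupancy falls
  below $10^{-13}$ and the microsimulation caps at 10,000 cycles with an
  error, so a non-convergent configuration is rejected rather than
  silently truncated.
* Ophthalmology "biannual" screening is read as every two years
  (0.5/yr), in deliberate contrast to dentistry's twice annually; it is a
  config value, not a constant.
* The dermatology entry age defaults to 50 with 48 available in config —
  both appear in the source material; the discrepancy is noted, not
  resolved.
* Scale choices in the shipped analyses: PSA at 200 × 500 and sweeps at
  500 individuals per grid point, a size at which replicate means are
  stable to a few percent while the full pipeline runs in about a minute;
  the engine defaults remain 1000 × 1000.

## Limitations

Cycle length is fixed at one year (sub-annual schedules are folded into
the cycle as repeated applications); there are no tunnel states,
semi-Markov sojourn times, or multi-way (>2 strategy) frontiers; expected
value of information is out of scope. CIs are computed over PSA replicate
means, not pooled individual draws — an explicit choice where the
convention is ambiguous.
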
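# markovscreen

Markov microsimulation of imperfect diagnostic screening — and whether it
pays off.

AI decision-support systems that read skin photographs, dental radiographs
or fundus images change two things about a screening programme: the
sensitivity/specificity of detection, and the cost of every test (a
per-use fee). `markovscreen` models that trade-off end to end, from the
payer perspective, for analysts doing model-based health-economic
evaluation: it simulates individuals (or single teeth) through annual-cycle
health states under periodic imperfect testing, accrues discounted costs
and effects, and computes the full incremental cost-effectiveness stack on
top. Three configurable model families are bundled — melanoma detection
(QALYs, USD), proximal caries detection at tooth level
(tooth-retention-years, EUR) and diabetic retinopathy grading
(utility-weighted QALYs, BRL) — plus a synthetic parameter generator, so
the whole pipeline runs out of the box on clearly labelled synthetic
inputs.

## The model in brief

Per cycle and individual: screening (tests due this cycle; positive with
probability *sens* in diseased states, *1 − spec* elsewhere; a decision
map turns results into actions — treatment routing, referral work-ups,
fees), then state rewards, then one transition drawn from age- and
treatment-dependent rows, with background mortality composed as a
competing risk. Costs and effects discount as *x*/(1 + *r*)^*t* (cycle 0
undiscounted, *r* = 3% default).

For two arms (AI vs standard of care) compared under **common random
numbers**:

- **ICER** = Δ*c*/Δ*e*, always with a dominance flag (`dominant`,
  `dominated`, `undefined`) since bare negative ratios are ambiguous;
- **net benefit** = WTP × Δ*e* − Δ*c*; the **CEAC** is the fraction of
  probabilistic-sensitivity-analysis replicates with positive net benefit
  at each willingness-to-pay;
- **PSA**: beta/gamma/uniform parameter distributions fitted to reported
  means and 95% CIs, *n*<sub>psa</sub> parameter draws ×
  *n*<sub>ind</sub> individuals, percentile CIs over replicate means;
- **one-way sweeps** over the AI fee and the discount rate (0–10%), with
  dominance-flip thresholds refined by bisection;
- **PPP conversion** at the 2020 rates (0.746 EUR, 2.362 BRL per USD) and
  the WHO 3×-GDP-per-capita ceiling.

Every stochastic result is backed by an exact analytic cohort solver
(`solve_cohort_analytic()`) that propagates occupancy vectors and folds
screening into composite transition rows in expectation — an independent
oracle the test suite holds the microsimulation to.

## Worked example

A probabilistic comparison of AI-assisted vs standard caries detection on
a synthetic parameter set (50 parameter draws × 200 teeth here; defaults
are 1000 × 1000):

```r
library(markovscreen)

g <- generate_default_params("dentistry", seed = 1)
model <- use_case_model("dentistry", g$params)
psa <- run_psa(model, g$distributions, n_psa = 50, n_individuals = 200,
               seed = 7)
psa
#> <psa_result> dentistry  n_psa = 50  n_individuals = 200  seed = 7
#> # A tibble: 4 × 5
#>   arm      quantity  mean lower upper
#>   <chr>    <chr>    <dbl> <dbl> <dbl>
#> 1 ai       cost     628.  567.  707.
#> 2 ai       effect    29.1  28.5  29.6
#> 3 standard cost     134.   87.3 186.
#> 4 standard effect    28.1  26.9  29.0
#>   ICER (of means): 509  [none]
```

Each row is a per-tooth lifetime mean with a 2.5–97.5% percentile
interval over the 50 replicates. Under these *synthetic* parameters the AI
arm buys about one extra discounted tooth-retention-year (29.1 vs 28.1)
at roughly 494 EUR extra cost — the twice-yearly 8 EUR fee compounds over
a ~70-year horizon — so AI is cost-effective only for payers valuing a
retention-year above the ~509 EUR ICER. The acceptability curve says the
same in probability terms:

```r
ceac(psa$draws, c(0, 500, 1000, 5000))
#> # A tibble: 4 × 2
#>     wtp p_cost_effective
#>   <dbl>            <dbl>
#> 1     0             0
#> 2   500             0.38
#> 3  1000             0.9
#> 4  5000             1
```

And the deterministic break-even toy — 4 lifetime tests against 64 units
of avoidable late-treatment cost — locates the fee at which AI stops being
dominant:

```r
toy <- build_fee_threshold_toy(treatment_savings = 64, n_tests = 4)
sw <- one_way_sweep(toy, "fee", seq(0, 32, 8), n = 50, seed = 1)
find_threshold(sw)   # bisection to 0.01
#> [1] 15.99609
```

## Analysis workflow

The `analysis/` scripts are thin numbered drivers over the package; each
prints what it found and writes tables under `results/`:

| script | what it does |
|---|---|
| `01_generate_parameters.R` | synthetic parameter/distribution sets → `results/params/*.yaml` |
| `02_known_truth_validation.R` | closed forms and analytic oracle vs microsimulation |
| `03_run_psa.R` | PSA per use case, summary with PPP conversion |
| `04_acceptability.R` | CEACs and the WHO ceiling |
| `05_sensitivity.R` | fee/discount sweeps and dominance thresholds |

Run them in order from the repository root:
`for s in analysis/0*.R; do Rscript "$s"; done`.

## Documentation

The methods vignette
(`vignettes/ai-screening-cost-effectiveness.Rmd`) describes the model
structure and assumptions, the common-random-numbers design, the
distribution fitting, what the synthetic generator does and does not
emulate, and the numerical choices. Function-level documentation lives in
the roxygen comments in `R/`.
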
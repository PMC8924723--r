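Package: markovscreen
Title: Markov Microsimulation of Imperfect Diagnostic Screening and Its
    Cost-Effectiveness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time Markov microsimulation of individuals (or teeth)
    moving through health states under periodic diagnostic screening with
    imperfect sensitivity and specificity, plus the incremental
    cost-effectiveness stack built on top of it: discounted cost and effect
    accrual, an exact analytic cohort solver used as a cross-check,
    incremental cost-effectiveness ratios with dominance flags, net monetary
    benefit, cost-effectiveness acceptability curves, probabilistic
    sensitivity analysis with beta/gamma/uniform parameter distributions,
    one-way sweeps with threshold detection, and purchasing-power-parity
    currency conversion. Ships three configurable screening model families
    (melanoma detection, proximal caries detection at tooth level, diabetic
    retinopathy grading) and a synthetic parameter generator producing
    internally consistent parameter sets and known-truth scenarios with
    closed-form reference values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    rlang,
    tibble
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
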
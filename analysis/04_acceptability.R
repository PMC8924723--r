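#!/usr/bin/env Rscript
# Cost-effectiveness acceptability curves from the CE draws written by
# 03_run_psa.R: for each willingness-to-pay ceiling, the probability that
# the AI-assisted arm has the higher net benefit. Also evaluates the WHO
# 3-x-GDP-per-capita ceiling for the Brazilian (ophthalmology) setting.

library(markovscreen)

for (uc in c("dermatology", "dentistry", "ophthalmology")) {
  draws <- read.csv(file.path("results", paste0("ce_draws_", uc, ".csv")))
  wtp <- seq(0, 1e5, by = 1000)
  curve <- ceac(draws, wtp)
  write.csv(curve, file.path("results", paste0("ceac_", uc, ".csv")),
            row.names = FALSE)
  p0 <- curve$p_cost_effective[curve$wtp == 0]
  p_hi <- curve$p_cost_effective[curve$wtp == 1e5]
  message(sprintf(
    "%-13s P(AI cost-effective): %.2f at WTP 0 -> %.2f at WTP 100k",
    uc, p0, p_hi))
}

# WHO ceiling in the Brazilian setting, per capita GDP in 2020 BRL (PPP)
gdp_brl <- 14563
ceil_brl <- who_threshold(gdp_brl)
draws <- read.csv("results/ce_draws_ophthalmology.csv")
p_who <- ceac(draws, ceil_brl)$p_cost_effective
message(sprintf(
  "ophthalmology at the WHO ceiling (3 x %d = %d BRL/QALY): P(AI cost-effective) = %.2f",
  gdp_brl, ceil_brl, p_who))
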
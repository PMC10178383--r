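# milkTEQ

Dietary risk assessment of dioxins (PCDD/Fs) and polychlorinated biphenyls
(PCBs) in cow milk, for food-safety assessors and monitoring laboratories.
The package covers the full chain from congener-level occurrence data to
population risk statements:

* **TEQ aggregation** — WHO-2005 TEF-weighted toxic equivalents per sample
  for the 17 PCDD/F and 12 dioxin-like PCB congeners, plus the unweighted
  sum of the 6 indicator PCBs, under lower/middle/upper-bound (0, ½LOQ,
  LOQ) substitution of non-detects.
* **Compliance screening** — EU maximum levels (2 / 4 pg TEQ/g fat,
  40 ng/g fat) and action levels, with per-limit flags and margins.
* **Descriptive statistics** — summaries by region/year, inter-survey
  percent variation, congener profiles (% contribution to total TEQ), fat
  vs contamination Spearman correlation, t/ANOVA+Tukey group comparisons.
* **Deterministic screening (first tier)** — estimated weekly intakes
  `EWI = C × M × F / 100` (pg TEQ/kg bw/week) and their percent of the
  tolerable weekly intake (TWI, 2 pg TEQ/kg bw/week) across age groups ×
  milk types, with escalation flags.
* **Probabilistic refinement (second tier)** — `exposure_model()`, a
  lognormal product model of contamination × consumption with fixed milk
  fat: seeded 50,000-iteration Monte Carlo percentile tables and
  TWI-exceedance probabilities, checked against the closed-form lognormal
  product distribution.
* **Synthetic surveys** — a calibrated generator reproducing the
  statistical structure of a two-region bulk-tank monitoring campaign, so
  every stage is testable without confidential monitoring data.

## Worked example

```r
library(milkTEQ)

## a calibrated synthetic survey: 214 samples, two regions, one sample
## constructed above the 4 pg TEQ/g fat maximum level
sv  <- generate_survey(survey_config(), seed = 1)
teq <- compute_teq(sv, scenario = "UB")
mean(teq$total_teq)
#> [1] 0.7785908
sum(!check_compliance(teq)$compliant)
#> [1] 1

## first tier: deterministic screening at C = 0.78 pg TEQ/g fat
st <- screening_table(contamination = 0.78)
st[st$age_group == "infants" & st$milk_type == "whole",
   c("ewi_mean", "ewi_p95", "pct_twi_mean", "pct_twi_p95")]
#>   ewi_mean  ewi_p95 pct_twi_mean pct_twi_p95
#> 2 6.392295 15.23040     319.6148    761.5199
```

An infant with mean whole-milk consumption ingests an estimated 6.39 pg
TEQ per kg body weight per week — 320% of the tolerable weekly intake;
high (P95) consumers reach 762%. Cells like this are escalated to the
probabilistic tier:

```r
m <- exposure_model(
  contamination = fit_lognormal_moments(0.78, 0.55),     # survey mean ± SD
  consumption   = fit_lognormal_mean_p95(234.15, 557.89),# mean & P95 intake
  fat_content   = 3.5, twi = 2, label = "infants/whole"
)
exceedance_prob(m)          # closed form: product of lognormals
#> [1] 0.7909738
sim <- simulate(m, nsim = 50000, seed = 42)
sim$exceedance_prob         # Monte Carlo, bit-reproducible under the seed
#> [1] 0.78856
round(sim$ewi_percentiles, 2)
#>   10%   20%   30%   40%   50%   60%   70%   80%   90% 
#>  1.28  1.93  2.60  3.32  4.18  5.26  6.76  9.03 13.57
```

About 79% of simulated infant weekly intakes from whole milk exceed the
TWI: the deterministic "320% of TWI" point estimate becomes a probability
statement, and the percentile grid shows the median intake (4.2 pg TEQ/kg
bw/week) already more than twice the TWI. `run_pipeline()` chains all stages —
TEQ → compliance → summaries → screening → Monte Carlo for the escalated
cells — and writes report CSVs plus a JSON provenance record.

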
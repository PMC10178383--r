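Package: milkTEQ
Title: Dioxin and PCB Exposure Assessment from Cow Milk Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toxic-equivalency (TEQ) aggregation of congener-level dioxin
    (PCDD/F) and polychlorinated biphenyl (PCB) occurrence data in cow milk
    under lower/middle/upper-bound treatment of non-detects, screening
    against European maximum and action levels, deterministic estimated
    weekly intake (EWI) screening for population age groups, and
    probabilistic refinement via a seeded Monte Carlo lognormal exposure
    model with closed-form results for the product distribution, percentile
    tables and tolerable-weekly-intake exceedance probabilities. Includes a
    calibrated synthetic survey generator emulating a two-region bulk-tank
    milk monitoring campaign with left-censored congener concentrations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
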
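Package: vitdmr
Title: Nonlinear Mendelian Randomization of Vitamin D Status and Brain Health
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Observational and Mendelian-randomization (MR) analysis of serum
    25-hydroxyvitamin D [25(OH)D] against dementia, stroke and brain-volume
    outcomes, built around a nonlinear MR workflow: a weighted genetic risk
    score instrument, instrument-free residual stratification, localized
    average causal effect (LACE) estimation per stratum, fractional-polynomial
    meta-regression of the LACE estimates, and reconstruction of the odds-ratio
    dose-response curve with a reference at 50 nmol/L. Includes progressively
    adjusted kinship-weighted linear and Cox observational models, two-sample
    MR estimators (random-effects IVW, MR-Egger, weighted median, weighted
    mode, MR-PRESSO), the potential impact fraction for correcting vitamin D
    deficiency, and a seeded synthetic-cohort generator that emulates the
    statistical structure of the analysis so the whole pipeline is testable
    without restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
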
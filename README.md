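# vitdmr

Observational and Mendelian-randomization (MR) analysis of serum
25-hydroxyvitamin D [25(OH)D] against dementia, stroke and brain-volume
outcomes, centred on **nonlinear MR**: the workflow that asks not "does
vitamin D affect dementia risk?" but "*over which part of the exposure
range* does it?". The motivating epidemiological finding is a threshold
effect — excess dementia risk concentrated below ~50 nmol/L (the clinical
sufficiency cut-off), with little further benefit above it.

The package is aimed at biostatisticians and genetic epidemiologists who
want the full pipeline — instrument construction, observational models,
pleiotropy-robust linear MR, stratified nonlinear MR, and the public-health
translation — as tested, reusable functions. Because the individual-level
cohort data such analyses use are access-restricted, `vitdmr` ships a
seeded synthetic-cohort generator that emulates the statistical structure
the analysis assumes, so every stage runs and is tested end to end without
any download.

## The model

**Instrument.** A weighted genetic risk score over 35 independent common
variants (MAF > 5%), `GRS_i = Σ_j w_j · dosage_ij`, with weights from an
independent GWAS, calibrated so the score explains ~2.8% of exposure
variance. The *instrument-free exposure* is the residual of measured
25(OH)D on the GRS, re-centred to the nmol/L scale.

**Nonlinear MR.** Individuals are ranked into K = 40 equal-size strata of
the instrument-free exposure. Within stratum k, the localized average
causal effect (LACE) is the ratio of the GRS–outcome to the GRS–exposure
association:

    LACE_k = beta_GY(k) / beta_GX(k),   se_k = se(beta_GY(k)) / |beta_GX(k)|

which estimates the derivative h′(x_k) of the causal log-odds dose–response
h(x) at the stratum's mean exposure. A fractional polynomial for h (powers
from {−2, −1, −0.5, 0, 0.5, 1, 2, 3}; power 0 = ln x) is fitted by
precision-weighted meta-regression of the LACE estimates on stratum means,
strata with a deviant first-stage slope (outside the 3-sigma band of the
pooled GRS–exposure association) flagged and removed. The curve is
reported as `OR(x) = exp(h(x) − h(50))`, anchored at the 50 nmol/L
reference, with seeded parametric confidence bands.

**Around the core.** Progressively adjusted linear (brain volumes,
log-transformed white-matter hyperintensity) and Cox (dementia, stroke)
observational models weighted by 1 − kinship coefficient, with quadratic
nonlinearity and likelihood-ratio interaction tests; two-sample estimators
(random-effects IVW, MR-Egger, weighted median, weighted mode, MR-PRESSO);
stratified linear MR across clinical 25(OH)D categories; and the potential
impact fraction

    PIF = (Σ RR(x_i) − Σ RR(max(x_i, 50))) / Σ RR(x_i)

— the fraction of cases preventable by raising everyone below the
threshold up to it.

## Worked example

```r
library(vitdmr)

params <- sim_params(n_individuals = 200000, seed = 7)
panel  <- simulate_panel(params)          # 35 calibrated instruments
cohort <- simulate_cohort(panel, params)  # exposures, covariates, outcomes

diag <- instrument_diagnostics(cohort$grs, cohort$vitd)
obs  <- fit_continuous(cohort, model_spec("dementia", "cox"))

strata <- stratify_quantiles(diag$residuals, 40)
laces  <- stratum_lace(cohort, strata)
curve  <- fit_fp(laces)                   # fractional-polynomial dose-response
nt     <- test_nonlinearity(laces)
o25    <- or_at(curve, 25)

sm  <- stratified_mr(cohort, panel, methods = "ivw_re")
pif <- compute_pif(cohort$vitd, curve, threshold = 50, n_bootstrap = 500)
```

Output (deterministic for this seed):

```
GRS R2 = 0.0275, F = 5653
Observational HR per 10 nmol/L: 0.64 (95% CI 0.63, 0.65), P-nonlinear = 1.6e-51
FP degree 1, powers 0; P-nonlinearity (FP vs linear) = 0.015
OR at 25 vs 50 nmol/L: 2.95 (95% CI 2.23, 3.92)
Stratified IVW OR per 10 nmol/L, <25 stratum: 0.55 (95% CI 0.44, 0.68)
PIF: 49.6% (95% CI 34.6%, 63.6%) of cases preventable by raising
  99987 of 200000 exposures to 50 nmol/L (500 bootstrap, seed 1)
```

Reading it: the GRS is a strong instrument (F ≫ 10) explaining 2.8% of
exposure variance as calibrated. The observational hazard ratio (0.64 per
10 nmol/L) is inflated by the simulated confounding; the MR analyses see
through it. The fractional-polynomial test rejects linearity, the odds of
dementia at 25 nmol/L are ~3-fold those at 50 nmol/L on the fitted curve,
and within the deficient (<25 nmol/L) stratum higher 25(OH)D is protective
(IVW OR 0.55 per 10 nmol/L) — the generator's threshold dose–response,
recovered. The PIF translates the curve into the preventable fraction of
cases under this (deliberately strong) simulated effect.

The whole pipeline, driven by one config, is also available as
`run_pipeline()` or from a shell via
`Rscript inst/scripts/vitdmr-pipeline.R all --config cfg.yaml`; it writes
the observational results table, per-method MR JSON, stratum-LACE and
curve TSVs, the PIF JSON and a seed/hash manifest.

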
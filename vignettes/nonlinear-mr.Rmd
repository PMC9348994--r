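---
title: "Nonlinear Mendelian randomization of vitamin D status: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlinear Mendelian randomization of vitamin D status: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitdmr)
```

## The question and the estimand

Serum 25-hydroxyvitamin D [25(OH)D] is observationally associated with
dementia, stroke and brain morphometry, but those associations are heavily
confounded: frailty, time spent outdoors, diet and socioeconomic position
all move both vitamin D status and brain health. Mendelian randomization
(MR) replaces the measured exposure with genetic variation that raises
25(OH)D lifelong and is (by Mendel's laws) independent of those
confounders. The specific scientific claim of interest is *nonlinear*: a
threshold dose–response in which risk rises only below ~50 nmol/L, the
clinical sufficiency cut-off. A linear MR coefficient averages over the
whole exposure range and can miss such an effect entirely; the estimand
here is the causal log-odds function $h(x)$ itself, reported as
$\mathrm{OR}(x) = \exp\{h(x) - h(50)\}$.

## The nonlinear MR procedure

1. **Instrument.** A weighted genetic risk score (GRS) over $J = 35$
   independent common variants, weights taken from a GWAS independent of
   the analysis cohort. `instrument_diagnostics()` reports $R^2$ and
   $F = R^2 (n-2)/(1-R^2)$.
2. **Instrument-free exposure.** The residual of measured 25(OH)D on the
   GRS, re-centred by adding back the sample mean so that clinical
   thresholds (25, 50 nmol/L) keep their meaning. Stratifying on the
   *measured* exposure would condition on a collider (the exposure is
   downstream of both the instrument and the confounders); stratifying on
   the instrument-free residual does not. Because the GRS explains only
   2.8% of exposure variance, the residual tracks the measured exposure
   almost perfectly — in-sample, exactly
   $\mathrm{corr} = \sqrt{1 - R^2} \approx 0.986$ — so the strata remain
   interpretable on the nmol/L scale.
3. **Stratification.** `stratify_quantiles()` assigns $K = 40$ equal-size
   rank strata (sizes differ by at most one; ties broken by stable input
   order).
4. **LACE.** Within stratum $k$, `stratum_lace()` estimates the
   GRS–exposure slope $\hat\beta_{GX,k}$ (linear, covariate-adjusted) and
   the GRS–outcome slope $\hat\beta_{GY,k}$ (logistic by default, matching
   an odds-scale report; Cox available via `family = "cox"`). The
   localized average causal effect
   $\widehat{\mathrm{LACE}}_k = \hat\beta_{GY,k}/\hat\beta_{GX,k}$, with
   first-order SE $\mathrm{se}(\hat\beta_{GY,k})/|\hat\beta_{GX,k}|$,
   estimates $h'(\bar x_k)$.
5. **Instrument-uniformity check.** The method assumes the GRS–exposure
   association is constant across strata. Strata whose
   $\hat\beta_{GX,k}$ falls outside the 99.7% (3-sigma) prediction band
   around the precision-weighted pooled slope are flagged; the primary
   curve is fitted with them removed (`remove_outliers = TRUE`). In
   practice the extreme strata fail this check — in the synthetic cohort
   the bottom stratum sits on the assay floor at 10 nmol/L, which
   mechanically attenuates its first-stage slope. Flag-and-report is the
   default; removal is config-controlled.
6. **Fractional-polynomial meta-regression.** `fit_fp()` models
   $h(x) = \sum_d \theta_d f_{p_d}(x)$ with $f_p(x) = x^p$ ($p \ne 0$),
   $f_0(x) = \ln x$, powers from the canonical set
   $\{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}$, repeated powers using the
   ln-augmented convention ($x^p$ and $x^p \ln x$). The LACE estimates are
   regressed on the *derivative* basis by weighted least squares (weights
   $1/\mathrm{se}_k^2$, coefficient covariance $(X'WX)^{-1}$ with known
   variances); the curve integrates back analytically, so
   $\mathrm{OR}(50) = 1$ exactly. Degree 1 scans all 8 powers, degree 2
   all 36 pairs; the automatic rule keeps degree 2 only when it beats the
   best degree 1 at $p < 0.05$ (chi-square, 2 df). Powers label the effect
   function $h$, not its derivative: a constant LACE profile selects power
   1 ($h$ linear), a $\theta/x$ profile selects power 0 ($h = \theta\ln x$).
7. **Nonlinearity tests.** `test_nonlinearity()` reports the
   fractional-polynomial test (best degree-1 vs the linear model,
   chi-square 1 df), the Wald test of the slope in a precision-weighted
   meta-regression of LACE on stratum mean (a "quadratic" test: a nonzero
   slope means $h$ has curvature), and Cochran's Q for LACE heterogeneity.
8. **Confidence bands and downstream use.** `effect_curve()`/`or_at()`
   draw the coefficients from their multivariate-normal distribution
   (10,000 seeded draws, percentile bands) — honest bands for the
   exponentiated integral, rather than a delta-method approximation.
   `compute_pif()` converts the curve into a potential impact fraction
   under shift-to-threshold (everyone below 50 nmol/L raised exactly to
   50), treating the odds ratio as a relative risk, defensible while
   cumulative incidence is a few percent; the joint bootstrap resamples
   individuals and redraws the curve coefficients in each replicate.

The supporting arms are standard and deliberately delegated: Cox models
with Efron ties and Schoenfeld-residual diagnostics through `survival`;
kinship weighting as case weights $1 -$ kinship coefficient; white-matter
hyperintensity log-transformed for skewness; the categorical analysis with
50–74.9 nmol/L as reference; two-sample estimators (random-effects IVW
with multiplicative inflation floored at 1, MR-Egger with its intercept
test, weighted median with interpolated crossing and parametric-bootstrap
SE, weighted mode with a modified-Silverman kernel bandwidth times
`phi = 1`, MR-PRESSO with leave-one-out residual-sum simulation, Bonferroni
outlier flags and a random-removal distortion null — all written from
their defining formulas and tested against independent brute-force
oracles).

## What the synthetic cohort emulates — and what it does not

`simulate_panel()`/`simulate_cohort()` generate the study conditions every
test runs under:

* 35 independent biallelic variants, EAF uniform on [0.05, 0.5]
  (MAF > 5% by construction), Hardy–Weinberg dosages; one dominant-weight
  variant alone in the "vitamin D transport" block mimics GC, the
  strongest single determinant of circulating 25(OH)D, so leave-block-out
  analyses have a block whose removal matters.
* Exposure: GRS + month-of-measurement sinusoid + a single standardized
  latent confounder + Gaussian noise, truncated to the assay-motivated
  [10, 240] nmol/L. `calibrate_weights()` rescales all weights by one
  analytic factor so the GRS explains exactly `target_r2` of the variance
  budget; truncation affects the realized sample $R^2$ by well under the
  ±0.002 tolerance at the default mean/SD.
* Dementia: exponential time-to-event with piecewise-linear log-hazard in
  25(OH)D — slope `causal_slope_below_knot` below 50 nmol/L, zero above —
  plus confounder and age terms; independent exponential dropout and
  administrative censoring at 10.9 years. Stroke: same machinery with zero
  causal slope, so its observational association is pure confounding.
  Brain volumes: age decline plus an *inverted-U* in the confounder and no
  causal 25(OH)D term, reproducing the U-shaped observational pattern
  without causality.

Key parameter choices, made once:

* **Exposure mean 50, SD 20 nmol/L** — the deficiency bins (<25, 25–50)
  are well populated (~10% and ~38%); the source cohorts do not publish a
  mean, so this is a plausible stand-in, configurable.
* **`causal_slope_below_knot = -0.05`** log-hazard per nmol/L. The two
  published anchors for the deficiency effect are mutually inconsistent
  (a curve odds ratio of 1.54 at 25 vs 50 nmol/L implies ~0.017/nmol/L;
  a stratified IVW OR of 0.35 per 10 nmol/L implies ~0.105/nmol/L);
  −0.05 sits between them and gives the stratified and curve analyses a
  clearly detectable contrast at the simulated scale.
* **`baseline_hazard = 1e-3`/year** — cumulative dementia incidence ~2%
  over 10.9 years at the default ages, the order observed in large
  middle-aged cohorts.
* **Confounding** −8 nmol/L and +0.4 log-hazard per confounder SD: "poor
  health" lowers vitamin D and raises risk, making the observational
  hazard ratio visibly too protective while MR stays null where it should.
* **Season amplitude 8 nmol/L** — an invented but physiologic annual
  swing; its variance is part of the analytic calibration budget.

What the generator deliberately does **not** emulate: linkage
disequilibrium between instruments (they are independent by design),
population stratification, dosage-imputation uncertainty, non-proportional
hazards (the exponential model satisfies the Cox assumptions by
construction), assay batch effects, and any real MRI measurement process
(volumes are drawn directly). Passing tests therefore demonstrate that the
*estimators* recover the truths of this statistical structure — not that
real cohort data are free of those further complications.

## Numerical choices and degenerate inputs

Weighted-least-squares solves use Cholesky-based normal equations;
candidate fractional polynomials whose design is numerically singular are
skipped in the scan. The exposure floor at 10 nmol/L guarantees positive
arguments for all powers and logs. Quantile strata break ties by input
order, making stratification deterministic. Zero-variance scores, zero
exposure betas, empty strata, zero-event strata, bins that miss part of
the exposure support, single-level interaction modifiers and
panel-emptying block exclusions are all refused with named errors rather
than propagating NaNs. All stochastic steps (bootstrap SEs, MR-PRESSO
simulations, curve draws, PIF bootstrap) take explicit seeds; the same
seed reproduces results bit-for-bit, and the pipeline writes a per-artifact
MD5 manifest.

## Known limitations

* The fractional-polynomial family has smoothly varying derivatives, so a
  hard threshold is approximated, not represented: fitted curves spread
  some of the below-knot decline above the knot (the fitted OR at 75 vs 50
  nmol/L sits below 1 even when the generating effect is exactly zero
  there, once the below-knot effect is strong enough to detect). This is a
  property of the method, visible only because the simulator knows the
  truth; with real data the curve above the knot should be read with that
  bias in mind.
* The residual-stratification design assumes a uniform instrument effect
  across strata; the 3-sigma flag is a pragmatic operationalization, and
  the assay floor guarantees the bottom stratum violates it.
* First-order (delta-method) SEs for Wald ratios and LACE ignore
  exposure-side uncertainty; adequate here because the per-stratum first
  stage is strong, but not for weak instruments.
* MR-PRESSO's global simulation is conditional on the observed
  leave-one-out fits and runs slightly anti-conservative (~8% rejection at
  nominal 5% in the null calibration used by the tests) — consistent with
  its use as a screening diagnostic rather than a confirmatory test.
* The PIF inherits the odds-ratio-as-relative-risk approximation and the
  curve's extrapolation behaviour below the lowest stratum mean.

## Problem sizes used by the test suite

Unit tests run on cohorts of 300–100,000 individuals; the statistical
acceptance checks use the sizes at which their properties are stable:
n = 400,000 for the residual-correlation identity (where the 3-decimal
rounding band is several sampling SDs wide), n = 200,000 with 50 seeded
replicates for threshold recovery, n = 50,000 with 25 replicates for the
confounded-stroke null, 500 replicates for the type-I-error calibrations,
and 50 replicates for MR-PRESSO outlier recovery. These choices are the
package's own trade-off between Monte-Carlo error and runtime.
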
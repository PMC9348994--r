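#' Simulation parameters for the synthetic cohort
#'
#' Bundles every tunable of the synthetic-cohort generator. Defaults describe
#' a UK-style middle-aged cohort: 35 independent common variants whose
#' weighted genetic risk score (GRS) explains 2.8% of the variance of serum
#' 25(OH)D, an exposure centred at 50 nmol/L with SD 20 nmol/L, a seasonal
#' sinusoid, a single standardized latent confounder acting on both exposure
#' and outcomes, a dementia hazard with a piecewise-linear (threshold)
#' log-hazard in 25(OH)D that plateaus above the knot at 50 nmol/L, a stroke
#' hazard that is confounded but (by default) not causally affected by
#' 25(OH)D, and brain volumes driven by age and the confounder only.
#'
#' @param n_individuals cohort size.
#' @param n_variants number of instruments (default 35).
#' @param target_r2 fraction of exposure variance explained by the GRS
#'   (default 0.028).
#' @param exposure_mean,exposure_sd marginal mean and SD of 25(OH)D, nmol/L.
#' @param season_amplitude amplitude of the month-of-measurement sinusoid,
#'   nmol/L.
#' @param confounder_effect_exposure effect of one SD of the latent
#'   confounder on 25(OH)D, nmol/L.
#' @param knot threshold of the piecewise-linear causal dose-response,
#'   nmol/L (default 50).
#' @param causal_slope_below_knot log-hazard of dementia per nmol/L of
#'   25(OH)D below the knot (negative = protective).
#' @param causal_slope_above_knot log-hazard per nmol/L above the knot
#'   (default 0: plateau).
#' @param stroke_causal_slope linear log-hazard of stroke per nmol/L
#'   (default 0: stroke association is pure confounding).
#' @param confounder_effect_outcome log-hazard per SD of the confounder,
#'   applied to both dementia and stroke.
#' @param baseline_hazard events per person-year at the knot for an average
#'   individual.
#' @param followup_years administrative censoring horizon (default 10.9).
#' @param censoring_rate rate of the independent exponential loss to
#'   follow-up, per year.
#' @param seed integer seed controlling the whole generator.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_individuals = 10000L,
                       n_variants = 35L,
                       target_r2 = 0.028,
                       exposure_mean = 50,
                       exposure_sd = 20,
                       season_amplitude = 8,
                       confounder_effect_exposure = -8,
                       knot = 50,
                       causal_slope_below_knot = -0.05,
                       causal_slope_above_knot = 0,
                       stroke_causal_slope = 0,
                       confounder_effect_outcome = 0.4,
                       baseline_hazard = 1e-3,
                       followup_years = 10.9,
                       censoring_rate = 0.02,
                       seed = 1L) {
  p <- list(
    n_individuals = as.integer(n_individuals),
    n_variants = as.integer(n_variants),
    target_r2 = target_r2,
    exposure_mean = exposure_mean,
    exposure_sd = exposure_sd,
    season_amplitude = season_amplitude,
    confounder_effect_exposure = confounder_effect_exposure,
    knot = knot,
    causal_slope_below_knot = causal_slope_below_knot,
    causal_slope_above_knot = causal_slope_above_knot,
    stroke_causal_slope = stroke_causal_slope,
    confounder_effect_outcome = confounder_effect_outcome,
    baseline_hazard = baseline_hazard,
    followup_years = followup_years,
    censoring_rate = censoring_rate,
    seed = as.integer(seed)
  )
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  if (p$n_individuals < 1L) stop("n_individuals must be positive")
  if (p$n_variants < 1L) stop("n_variants must be positive")
  if (p$target_r2 < 0 || p$target_r2 >= 1)
    stop("target_r2 must lie in [0, 1)")
  if (p$exposure_sd <= 0) stop("exposure_sd must be positive")
  if (p$baseline_hazard < 0 || p$censoring_rate < 0 ||
      p$followup_years <= 0)
    stop("rates must be non-negative and followup_years positive")
  invisible(p)
}

# Variance budget of the exposure model. The sinusoid over uniform months has
# variance amplitude^2/2 exactly; the residual (assay + biology) noise picks
# up whatever the GRS, season and confounder do not account for.
exposure_variance_budget <- function(p) {
  total <- p$exposure_sd^2
  grs <- p$target_r2 * total
  season <- p$season_amplitude^2 / 2
  conf <- p$confounder_effect_exposure^2
  noise <- total - grs - season - conf
  if (noise <= 0)
    stop("target_r2 unreachable: season/confounder variance already exceeds ",
         "the non-genetic variance budget")
  list(total = total, grs = grs, season = season, conf = conf, noise = noise)
}
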
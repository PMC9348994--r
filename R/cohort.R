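#' Simulate an individual-level cohort from a variant panel
#'
#' Generates genotype dosages under Hardy-Weinberg equilibrium
#' (`Binomial(2, eaf)` independently per variant), a 25(OH)D exposure built
#' from the weighted GRS, a month-of-measurement sinusoid, a standardized
#' latent confounder and Gaussian noise — truncated to the assay-motivated
#' range \[10, 240\] nmol/L — plus exponential time-to-event outcomes for
#' dementia (piecewise-linear threshold log-hazard in 25(OH)D) and stroke
#' (linear slope, zero by default, so its observational association is pure
#' confounding), brain volumes with a confounder-driven inverted-U shape and
#' no causal 25(OH)D term, and a kinship weight `1 - kinship coefficient`.
#'
#' Follow-up is censored by an independent exponential dropout process and
#' administratively at `followup_years`. The same `params$seed` always
#' reproduces the identical table.
#'
#' @param panel a `variant_panel` from [simulate_panel()].
#' @param params the same [sim_params()] used to build the panel.
#' @return A `cohort_table` data frame: one row per individual with dosage
#'   columns (`dosage_<variant_id>`), `grs`, `vitd`, `confounder`,
#'   `season_month`, covariates (`age`, `sex`, `center`, `ethnicity`,
#'   `education`, `bmi`, `outdoor_time`, `illness`), event/time pairs for
#'   dementia and stroke, brain volumes (`total_volume`, `gray_volume`,
#'   `white_volume`, `hippocampal_volume`, `wmh`) and `kinship_weight`.
#' @export
simulate_cohort <- function(panel, params) {
  validate_sim_params(params)
  validate_panel(panel)
  if (nrow(panel) != params$n_variants)
    stop("panel has ", nrow(panel), " variants but params$n_variants is ",
         params$n_variants)

  n <- params$n_individuals
  J <- nrow(panel)
  set.seed(params$seed + 1L)

  dosages <- matrix(rbinom(n * J, 2L, rep(panel$eaf, each = n)),
                    nrow = n, ncol = J)
  colnames(dosages) <- paste0("dosage_", panel$variant_id)
  grs <- drop(dosages %*% panel$weight_exposure)

  season_month <- sample.int(12L, n, replace = TRUE)
  season <- params$season_amplitude * sin(2 * pi * (season_month - 1) / 12)
  confounder <- rnorm(n)

  budget <- if (params$target_r2 > 0) exposure_variance_budget(params) else {
    b <- params$exposure_sd^2 - params$season_amplitude^2 / 2 -
      params$confounder_effect_exposure^2
    if (b <= 0) stop("non-genetic variance budget exhausted")
    list(noise = b)
  }
  offset <- params$exposure_mean - sum(2 * panel$eaf * panel$weight_exposure)
  vitd <- offset + grs + season +
    params$confounder_effect_exposure * confounder +
    rnorm(n, 0, sqrt(budget$noise))
  vitd <- pmin(pmax(vitd, 10), 240) # assay floor / top analysis category

  age <- runif(n, 40, 70)
  sex <- factor(sample(c("female", "male"), n, replace = TRUE),
                levels = c("female", "male"))
  center <- factor(sample(paste0("center_", 1:6), n, replace = TRUE))
  ethnicity <- factor(sample(c("white", "asian", "black"), n, replace = TRUE,
                             prob = c(0.94, 0.03, 0.03)),
                      levels = c("white", "asian", "black"))
  education <- factor(sample(c("low", "intermediate", "high"), n,
                             replace = TRUE, prob = c(0.3, 0.4, 0.3)),
                      levels = c("low", "intermediate", "high"))
  bmi <- rnorm(n, 27, 4.5)
  outdoor_time <- pmax(rnorm(n, 3, 1.5), 0)
  illness <- rbinom(n, 1L, 0.12)

  # log-hazards; age acts on both outcomes so adjustment matters
  below <- pmin(vitd - params$knot, 0)
  above <- pmax(vitd - params$knot, 0)
  lh_dem <- log(params$baseline_hazard) +
    params$causal_slope_below_knot * below +
    params$causal_slope_above_knot * above +
    params$confounder_effect_outcome * confounder +
    0.05 * (age - 55)
  lh_str <- log(params$baseline_hazard) +
    params$stroke_causal_slope * (vitd - params$knot) +
    params$confounder_effect_outcome * confounder +
    0.05 * (age - 55)

  surv <- function(loghaz) {
    t_event <- rexp(n, rate = exp(loghaz))
    t_cens <- if (params$censoring_rate > 0)
      rexp(n, rate = params$censoring_rate) else rep(Inf, n)
    t_cens <- pmin(t_cens, params$followup_years)
    list(time = pmin(t_event, t_cens), event = as.integer(t_event <= t_cens))
  }
  dem <- surv(lh_dem)
  str_ <- surv(lh_str)

  # volumes: age decline + inverted-U in the confounder, no causal vitd term
  total_volume <- 1160 - 1.5 * (age - 55) - 5 * confounder^2 + rnorm(n, 0, 40)
  gray_volume <- 640 - 1.2 * (age - 55) - 3 * confounder^2 + rnorm(n, 0, 25)
  white_volume <- 520 - 0.5 * (age - 55) - 2 * confounder^2 + rnorm(n, 0, 25)
  hippocampal_volume <- 4 - 0.01 * (age - 55) - 0.02 * confounder^2 +
    rnorm(n, 0, 0.3)
  wmh <- exp(1.2 + 0.03 * (age - 55) + 0.2 * confounder^2 + rnorm(n, 0, 0.6))

  kin <- ifelse(runif(n) < 0.1, runif(n, 0.001, 0.25), 0)
  kinship_weight <- 1 - kin

  cohort <- data.frame(
    id = seq_len(n), dosages, grs = grs, vitd = vitd,
    confounder = confounder, season_month = season_month,
    age = age, sex = sex, center = center, ethnicity = ethnicity,
    education = education, bmi = bmi, outdoor_time = outdoor_time,
    illness = illness,
    dementia_event = dem$event, dementia_time = dem$time,
    stroke_event = str_$event, stroke_time = str_$time,
    total_volume = total_volume, gray_volume = gray_volume,
    white_volume = white_volume, hippocampal_volume = hippocampal_volume,
    wmh = wmh, kinship_weight = kinship_weight,
    stringsAsFactors = FALSE
  )
  class(cohort) <- c("cohort_table", "data.frame")
  cohort
}

#' Extract the dosage matrix from a cohort table
#' @param cohort a `cohort_table`.
#' @return Integer matrix, individuals by variants, columns named by
#'   variant id.
#' @export
dosage_matrix <- function(cohort) {
  cols <- grep("^dosage_", names(cohort), value = TRUE)
  if (!length(cols)) stop("cohort has no dosage_ columns")
  m <- as.matrix(cohort[cols])
  colnames(m) <- sub("^dosage_", "", cols)
  m
}

#' Write / read a cohort table as gzip-compressed TSV
#' @param cohort a `cohort_table`.
#' @param path output path (".tsv.gz" recommended).
#' @return `path`, invisibly (writer); a `cohort_table` (reader).
#' @export
write_cohort <- function(cohort, path) {
  con <- gzfile(path, "w")
  on.exit(close(con))
  utils::write.table(cohort, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  for (col in intersect(c("sex", "center", "ethnicity", "education"),
                        names(x)))
    x[[col]] <- factor(x[[col]])
  class(x) <- c("cohort_table", "data.frame")
  x
}

#' Write a variant panel as summary-statistics TSV
#'
#' Column names match the summary-stats reader ([read_sumstats()]):
#' `variant_id`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#' `pval`, plus `block`.
#' @param panel a `variant_panel`.
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  out <- data.frame(
    variant_id = panel$variant_id,
    effect_allele = panel$effect_allele,
    other_allele = panel$other_allele,
    eaf = panel$eaf,
    beta = panel$weight_exposure,
    se = panel$se_exposure,
    pval = panel$pval_exposure,
    block = panel$block,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
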
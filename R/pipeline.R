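#' Assemble and validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list and fills defaults. Top-level
#' blocks: `paths` (`output_dir`, optional `cohort`, `panel` inputs),
#' `simulation` (fields of [sim_params()]; used when no cohort path is
#' given), `analysis` (`k_strata`, `reference`, `pif_threshold`,
#' `stratified_bounds`, `remove_outlier_strata`, `covariates_mr`,
#' `categorical_bins`, `n_bootstrap`, `fp_degree`) and `seeds` (one per
#' stochastic stage: `simulate`, `median_mode`, `presso`, `curve`, `pif`).
#'
#' @param config path to a YAML file, or a named list.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  defaults <- list(
    paths = list(output_dir = tempfile("vitdmr_run_"), cohort = NULL,
                 panel = NULL),
    simulation = list(),
    analysis = list(k_strata = 40L, reference = 50, pif_threshold = 50,
                    stratified_bounds = c(25, 50, 75),
                    remove_outlier_strata = TRUE,
                    covariates_mr = c("age", "sex"),
                    categorical_bins = c(10, 25, 50, 75, 100, 125, 240),
                    n_bootstrap = 500L, fp_degree = NULL,
                    outcome = "dementia"),
    seeds = list(simulate = 1L, median_mode = 11L, presso = 21L,
                 curve = 31L, pif = 41L)
  )
  merged <- utils::modifyList(defaults, config)
  a <- merged$analysis
  if (a$k_strata < 3) stop("analysis$k_strata must be >= 3")
  if (any(diff(a$stratified_bounds) <= 0))
    stop("analysis$stratified_bounds must be strictly increasing")
  for (s in names(merged$seeds))
    if (!is.numeric(merged$seeds[[s]]))
      stop("seeds$", s, " must be an integer")
  class(merged) <- "pipeline_config"
  merged
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing required columns: ",
         paste(miss, collapse = ", "))
  invisible(df)
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> input filters -> instruments/GRS diagnostics ->
#' observational models -> linear two-sample MR (all estimators +
#' MR-PRESSO) -> nonlinear MR (stratification, LACE, fractional
#' polynomial, curve) -> potential impact fraction. Writes, under
#' `paths$output_dir`: an observational `table2.tsv` (outcome x adjustment
#' level), `linear_mr.json`, `strata_lace.tsv`, `curve.tsv`,
#' `nonlinear_mr.json`, `pif.json` and `run_log.txt` with seeds, filter
#' counts and per-artifact MD5 hashes. Deterministic given the seeds block.
#'
#' Input filters, applied before any fit: 25(OH)D outside the reportable
#' limits set missing, brain-volume outliers beyond 3 SD excluded, and
#' (when a `prevalent` column exists) prevalent dementia/stroke cases
#' excluded.
#'
#' @param config a [pipeline_config()] (or anything it accepts).
#' @return Invisibly, a list with the main result objects and file paths.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  out_dir <- cfg$paths$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("vitdmr pipeline run %s", format(Sys.time())),
                 sprintf("seeds: %s",
                         paste(names(cfg$seeds), unlist(cfg$seeds),
                               sep = "=", collapse = " ")))

  # --- inputs ---------------------------------------------------------
  if (!is.null(cfg$paths$cohort)) {
    cohort <- read_cohort(cfg$paths$cohort)
    require_columns(cohort, c("vitd", "grs", "dementia_event",
                              "dementia_time", "kinship_weight"),
                    "cohort table")
    panel <- if (!is.null(cfg$paths$panel)) {
      ss <- read_sumstats(cfg$paths$panel)
      p <- data.frame(variant_id = ss$variant_id,
                      effect_allele = ss$effect_allele,
                      other_allele = ss$other_allele, eaf = ss$eaf,
                      weight_exposure = ss$beta, se_exposure = ss$se,
                      pval_exposure = ss$pval,
                      block = if ("block" %in% names(ss)) ss$block
                              else "unassigned",
                      stringsAsFactors = FALSE)
      class(p) <- c("variant_panel", "data.frame"); p
    } else stop("paths$panel is required when paths$cohort is given")
  } else {
    sim_args <- cfg$simulation
    sim_args$seed <- cfg$seeds$simulate
    params <- do.call(sim_params, sim_args)
    panel <- simulate_panel(params)
    cohort <- simulate_cohort(panel, params)
    write_panel(panel, file.path(out_dir, "panel.tsv"))
    write_cohort(cohort, file.path(out_dir, "cohort.tsv.gz"))
    log_lines <- c(log_lines,
                   sprintf("simulated cohort: n=%d, J=%d",
                           nrow(cohort), nrow(panel)))
  }

  # --- filters --------------------------------------------------------
  cohort <- filter_exposure_limits(cohort)
  n_missing <- attr(cohort, "n_set_missing")
  cohort <- filter_volume_outliers(cohort)
  n_excluded <- attr(cohort, "n_excluded")
  n_prev <- 0L
  if ("prevalent" %in% names(cohort)) {
    n_prev <- sum(cohort$prevalent > 0)
    cohort <- cohort[cohort$prevalent == 0, , drop = FALSE]
  }
  log_lines <- c(log_lines, sprintf(
    "filters: %d exposures set missing, %d volume-outlier rows excluded, %d prevalent cases excluded",
    n_missing, n_excluded, n_prev))
  keep <- !is.na(cohort$vitd)
  cohort_cc <- cohort[keep, , drop = FALSE]

  # --- instruments ----------------------------------------------------
  diag <- instrument_diagnostics(cohort_cc$grs, cohort_cc$vitd)
  log_lines <- c(log_lines, sprintf(
    "instrument diagnostics: r2=%.4f, F=%.1f, n=%d",
    diag$diagnostics$r2, diag$diagnostics$f_stat, diag$diagnostics$n))

  # --- observational table -------------------------------------------
  outcomes <- list(
    list(name = "total_volume", family = "linear"),
    list(name = "gray_volume", family = "linear"),
    list(name = "white_volume", family = "linear"),
    list(name = "hippocampal_volume", family = "linear"),
    list(name = "wmh", family = "linear"),
    list(name = "dementia", family = "cox"),
    list(name = "stroke", family = "cox"))
  levels_ <- names(default_adjustment_sets())
  tab <- do.call(rbind, lapply(outcomes, function(oc) {
    ok <- oc$family == "linear" ||
      all(paste0(oc$name, c("_event", "_time")) %in% names(cohort_cc))
    if (oc$family == "linear" && !oc$name %in% names(cohort_cc)) ok <- FALSE
    if (!ok) return(NULL)
    do.call(rbind, lapply(levels_, function(lv) {
      r <- fit_continuous(cohort_cc,
                          model_spec(oc$name, oc$family,
                                     adjustment_level = lv))
      data.frame(outcome = oc$name, family = oc$family,
                 adjustment = lv, estimate = r$estimate,
                 ci_low = r$ci_low, ci_high = r$ci_high,
                 p_trend = r$p_trend, p_nonlinear = r$p_nonlinear,
                 n_used = r$n_used)
    }))
  }))
  obs_path <- file.path(out_dir, "table2.tsv")
  utils::write.table(tab, obs_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # --- linear two-sample MR ------------------------------------------
  a <- cfg$analysis
  h <- variant_associations(cohort_cc, panel, outcome = a$outcome,
                            covariates = a$covariates_mr)
  methods <- c("ivw_re", "egger", "weighted_median", "weighted_mode")
  linear <- lapply(methods, function(m)
    mr_estimate(h, m, n_boot = a$n_bootstrap,
                seed = cfg$seeds$median_mode))
  names(linear) <- methods
  presso <- mr_presso(h, n_sim = max(a$n_bootstrap, 100L),
                      seed = cfg$seeds$presso)
  lin_json <- c(lapply(linear, function(r)
    r[c("method", "estimate", "se", "ci_low", "ci_high", "p",
        "cochran_q", "q_df", "q_p", "egger_intercept",
        "egger_intercept_p", "n_variants_used")]),
    list(mr_presso = list(global_p = presso$global_p,
                          n_outliers = sum(presso$outliers$flagged),
                          distortion_p = presso$distortion_p)))
  lin_path <- file.path(out_dir, "linear_mr.json")
  jsonlite::write_json(lin_json, lin_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")

  # --- nonlinear MR ---------------------------------------------------
  diag2 <- instrument_diagnostics(cohort_cc$grs, cohort_cc$vitd)
  strata <- stratify_quantiles(diag2$residuals, a$k_strata)
  laces <- stratum_lace(cohort_cc, strata, covariates = a$covariates_mr,
                        outcome = a$outcome)
  lace_path <- file.path(out_dir, "strata_lace.tsv")
  utils::write.table(laces, lace_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  curve <- fit_fp(laces, degree = a$fp_degree,
                  remove_outliers = a$remove_outlier_strata,
                  reference = a$reference)
  nl_tests <- test_nonlinearity(laces,
                                remove_outliers = a$remove_outlier_strata)
  grid <- effect_curve(curve, seed = cfg$seeds$curve)
  curve_path <- file.path(out_dir, "curve.tsv")
  utils::write.table(grid, curve_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nl_json <- list(degree = curve$degree, powers = curve$powers,
                  theta = curve$theta,
                  theta_cov = curve$theta_cov,
                  reference = curve$reference,
                  p_fp = nl_tests$p_fp, p_quadratic = nl_tests$p_quadratic,
                  p_q = nl_tests$p_q,
                  n_strata_used = nrow(curve$laces_used),
                  outlier_strata = laces$index[laces$outlier_flag])
  nl_path <- file.path(out_dir, "nonlinear_mr.json")
  jsonlite::write_json(nl_json, nl_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  # --- PIF ------------------------------------------------------------
  pif <- compute_pif(cohort_cc$vitd, curve, threshold = a$pif_threshold,
                     n_bootstrap = a$n_bootstrap, seed = cfg$seeds$pif)
  pif_path <- file.path(out_dir, "pif.json")
  jsonlite::write_json(unclass(pif), pif_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  # --- manifest -------------------------------------------------------
  artifacts <- c(obs_path, lin_path, lace_path, curve_path, nl_path,
                 pif_path)
  md5 <- tools::md5sum(artifacts)
  log_lines <- c(log_lines, sprintf("R version: %s", R.version.string),
                 paste(basename(artifacts), unname(md5), sep = "  md5="))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(cohort = cohort_cc, panel = panel,
                 diagnostics = diag$diagnostics, observational = tab,
                 linear_mr = linear, mr_presso = presso, laces = laces,
                 curve = curve, nonlinearity = nl_tests, pif = pif,
                 paths = c(artifacts,
                           log = file.path(out_dir, "run_log.txt"))))
}
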
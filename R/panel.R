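#' Simulate a panel of genetic instruments for 25(OH)D
#'
#' Draws `n_variants` independent common biallelic variants (effect-allele
#' frequency in \[0.05, 0.5\], i.e. MAF > 5% by construction), assigns each a
#' per-allele effect on 25(OH)D and a functional-block label, and rescales
#' the weights (see [calibrate_weights()]) so that the weighted GRS explains
#' `target_r2` of the exposure variance. The first variant carries a
#' dominant weight and sits alone in the vitamin D transport block,
#' mimicking the GC (vitamin D binding protein) locus, the strongest single
#' determinant of circulating 25(OH)D.
#'
#' @param params a [sim_params()] object.
#' @return A `variant_panel` data frame with columns `variant_id`,
#'   `effect_allele`, `other_allele`, `eaf`, `weight_exposure`,
#'   `se_exposure`, `pval_exposure`, `block`.
#' @export
simulate_panel <- function(params) {
  validate_sim_params(params)
  J <- params$n_variants
  set.seed(params$seed)

  eaf <- runif(J, 0.05, 0.5)
  alleles <- c("A", "C", "G", "T")
  effect_allele <- sample(alleles, J, replace = TRUE)
  other_allele <- vapply(effect_allele,
                         function(a) sample(setdiff(alleles, a), 1L),
                         character(1))

  # raw (uncalibrated) per-allele effects; variant 1 dominates, as GC does
  w <- abs(rnorm(J, mean = 0.8, sd = 0.3))
  w <- pmax(w, 0.1)
  w[1] <- 3

  blocks <- c("vitamin D transport", "vitamin D synthesis",
              "vitamin D metabolism", "blood traits", "lipids", "other")
  block <- c("vitamin D transport",
             sample(blocks[-1], J - 1L, replace = TRUE))

  panel <- data.frame(
    variant_id = sprintf("rs%06d", seq_len(J) * 101L),
    effect_allele = effect_allele,
    other_allele = other_allele,
    eaf = eaf,
    weight_exposure = w,
    se_exposure = NA_real_,
    pval_exposure = NA_real_,
    block = block,
    stringsAsFactors = FALSE
  )
  panel <- calibrate_weights(panel, params)

  # plausible discovery-scale SEs / p-values for a reference GWAS of ~80k
  n_ref <- 80000
  panel$se_exposure <- params$exposure_sd /
    sqrt(n_ref * 2 * panel$eaf * (1 - panel$eaf))
  z <- ifelse(panel$se_exposure > 0,
              panel$weight_exposure / panel$se_exposure, 0)
  panel$pval_exposure <- 2 * pnorm(-abs(z))

  class(panel) <- c("variant_panel", "data.frame")
  panel
}

#' Calibrate instrument weights to a target variance explained
#'
#' Rescales all exposure weights by a single factor so that, analytically,
#' the GRS variance `sum(w^2 * 2 * eaf * (1 - eaf))` equals
#' `target_r2 * exposure_sd^2` — i.e. the GRS explains `target_r2` of the
#' exposure variance given the generator's season, confounder and noise
#' variance budget. With `target_r2 = 0` all weights become zero.
#'
#' @param panel a `variant_panel`.
#' @param params a [sim_params()] object; `target_r2` must be reachable
#'   given the non-genetic variance components.
#' @return The panel with rescaled `weight_exposure`.
#' @export
calibrate_weights <- function(panel, params) {
  stopifnot(is.data.frame(panel), nrow(panel) >= 1L)
  if (params$target_r2 == 0) {
    panel$weight_exposure <- 0
    return(panel)
  }
  budget <- exposure_variance_budget(params) # errors if unreachable
  var_dosage <- 2 * panel$eaf * (1 - panel$eaf)
  raw_var <- sum(panel$weight_exposure^2 * var_dosage)
  if (raw_var <= 0) stop("panel weights are all zero; cannot calibrate")
  panel$weight_exposure <- panel$weight_exposure *
    sqrt(budget$grs / raw_var)
  panel
}

validate_panel <- function(panel) {
  req <- c("variant_id", "effect_allele", "other_allele", "eaf",
           "weight_exposure")
  miss <- setdiff(req, names(panel))
  if (length(miss))
    stop("panel is missing columns: ", paste(miss, collapse = ", "))
  if (any(panel$eaf <= 0 | panel$eaf >= 1))
    stop("eaf must lie in (0, 1)")
  if (any(panel$effect_allele == panel$other_allele))
    stop("effect and other allele must differ")
  if (any(!is.finite(panel$weight_exposure)))
    stop("weights must be finite")
  invisible(panel)
}
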
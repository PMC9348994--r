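#' Read GWAS summary statistics
#'
#' Tab-delimited with header; required columns `variant_id`,
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`. Extra
#' columns (e.g. `block`) are kept.
#' @param path file path (plain or gzip).
#' @return A data frame of summary statistics.
#' @export
read_sumstats <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  req <- c("variant_id", "effect_allele", "other_allele", "eaf", "beta",
           "se", "pval")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("summary statistics at ", path, " are missing columns: ",
         paste(miss, collapse = ", "))
  x
}

#' Select genetic instruments from two independent GWAS
#'
#' Keeps variants present in both sources with minor allele frequency above
#' `maf_min`, a nominally significant replication association
#' (`pval < 0.05`) and a direction of effect consistent between discovery
#' and replication. Weights (and SEs, p-values) are taken from the
#' replication source, so the GRS weights are independent of the cohort in
#' which the score is applied.
#'
#' @param discovery,replication summary-statistics data frames
#'   ([read_sumstats()] layout), keyed by `variant_id`.
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @return A `variant_panel` of the retained instruments.
#' @export
select_instruments <- function(discovery, replication, maf_min = 0.05) {
  m <- merge(discovery, replication, by = "variant_id",
             suffixes = c("_disc", "_repl"))
  if (!nrow(m)) stop("no variants shared between discovery and replication")
  maf <- pmin(m$eaf_repl, 1 - m$eaf_repl)
  keep <- maf > maf_min &
    m$pval_repl < 0.05 &
    sign(m$beta_disc) == sign(m$beta_repl) &
    m$beta_disc != 0 & m$beta_repl != 0
  m <- m[keep, , drop = FALSE]
  if (!nrow(m)) stop("no variants survive instrument selection")
  panel <- data.frame(
    variant_id = m$variant_id,
    effect_allele = m$effect_allele_repl,
    other_allele = m$other_allele_repl,
    eaf = m$eaf_repl,
    weight_exposure = m$beta_repl,
    se_exposure = m$se_repl,
    pval_exposure = m$pval_repl,
    block = if ("block_repl" %in% names(m)) m$block_repl
            else if ("block_disc" %in% names(m)) m$block_disc
            else "unassigned",
    stringsAsFactors = FALSE
  )
  class(panel) <- c("variant_panel", "data.frame")
  panel
}

allele_complement <- function(a) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[a])
}

is_palindromic <- function(a1, a2) allele_complement(a1) == a2

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome effect estimates to the exposure effect allele for
#' two-sample MR. Outcome rows whose alleles are swapped (directly or on the
#' opposite strand) have their beta sign flipped and eaf reflected;
#' palindromic variants (A/T, C/G) with outcome eaf inside
#' `palindromic_window` are dropped as strand-ambiguous; allele pairs that
#' cannot be reconciled are dropped. Every row carries a
#' `harmonization_action` in `kept`, `flipped`, `dropped_palindromic`,
#' `dropped_mismatch`; downstream estimators use only kept/flipped rows.
#'
#' @param exposure,outcome summary-statistics data frames
#'   ([read_sumstats()] layout).
#' @param palindromic_window eaf interval treated as ambiguous for
#'   palindromic variants (default `c(0.40, 0.60)`).
#' @return A `harmonized_stats` data frame with columns `variant_id`,
#'   `effect_allele`, `other_allele`, `beta_exposure`, `se_exposure`,
#'   `eaf_exposure`, `beta_outcome`, `se_outcome`, `eaf_outcome`,
#'   `harmonization_action`.
#' @export
harmonize <- function(exposure, outcome, palindromic_window = c(0.40, 0.60)) {
  for (nm in c("effect_allele", "other_allele"))
    if (!nm %in% names(exposure) || !nm %in% names(outcome))
      stop("allele columns missing: ", nm)
  m <- merge(exposure, outcome, by = "variant_id",
             suffixes = c("_exposure", "_outcome"))
  if (!nrow(m)) stop("no shared variants to harmonize")

  ee <- toupper(m$effect_allele_exposure); oe <- toupper(m$other_allele_exposure)
  eo <- toupper(m$effect_allele_outcome); oo <- toupper(m$other_allele_outcome)

  same <- ee == eo & oe == oo
  swapped <- ee == oo & oe == eo
  comp_same <- allele_complement(ee) == eo & allele_complement(oe) == oo
  comp_swapped <- allele_complement(ee) == oo & allele_complement(oe) == eo
  palin <- is_palindromic(ee, oe)
  ambiguous <- palin &
    m$eaf_outcome >= palindromic_window[1] &
    m$eaf_outcome <= palindromic_window[2]
  # for unambiguous palindromic pairs strand is undecidable from alleles;
  # align by allele-frequency agreement instead
  palin_flip <- palin & !ambiguous &
    ((m$eaf_exposure < 0.5) != (m$eaf_outcome < 0.5))

  action <- rep("dropped_mismatch", nrow(m))
  action[same | comp_same] <- "kept"
  action[swapped | comp_swapped] <- "flipped"
  action[palin & (same | swapped | comp_same | comp_swapped)] <-
    ifelse(palin_flip[palin & (same | swapped | comp_same | comp_swapped)],
           "flipped", "kept")
  action[ambiguous] <- "dropped_palindromic"

  flip <- action == "flipped"
  beta_outcome <- ifelse(flip, -m$beta_outcome, m$beta_outcome)
  eaf_outcome <- ifelse(flip, 1 - m$eaf_outcome, m$eaf_outcome)

  h <- data.frame(
    variant_id = m$variant_id,
    effect_allele = m$effect_allele_exposure,
    other_allele = m$other_allele_exposure,
    beta_exposure = m$beta_exposure,
    se_exposure = m$se_exposure,
    eaf_exposure = m$eaf_exposure,
    beta_outcome = beta_outcome,
    se_outcome = m$se_outcome,
    eaf_outcome = eaf_outcome,
    harmonization_action = action,
    stringsAsFactors = FALSE
  )
  class(h) <- c("harmonized_stats", "data.frame")
  h
}

#' Rows of a harmonized table usable for estimation
#' @param h a `harmonized_stats` data frame.
#' @return The kept/flipped subset.
#' @export
harmonized_kept <- function(h) {
  h[h$harmonization_action %in% c("kept", "flipped"), , drop = FALSE]
}

#' Compute the weighted genetic risk score
#'
#' `score_i = sum_j dosage_ij * weight_j`, with missing dosages imputed as
#' `2 * eaf_j` (preserving the score expectation) before weighting.
#'
#' @param dosages numeric matrix (individuals x variants). If columns are
#'   named they are matched to `panel$variant_id`; otherwise column order
#'   must follow the panel.
#' @param panel a `variant_panel`.
#' @return Numeric vector of scores, one per individual.
#' @export
compute_grs <- function(dosages, panel) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != nrow(panel))
    stop("dosage matrix has ", ncol(dosages), " columns but panel has ",
         nrow(panel), " variants")
  if (!is.null(colnames(dosages))) {
    if (!all(panel$variant_id %in% colnames(dosages)))
      stop("dosage columns do not match panel variant ids")
    dosages <- dosages[, panel$variant_id, drop = FALSE]
  }
  if (anyNA(dosages)) {
    for (j in which(colSums(is.na(dosages)) > 0)) {
      miss <- is.na(dosages[, j])
      dosages[miss, j] <- 2 * panel$eaf[j]
    }
  }
  drop(dosages %*% panel$weight_exposure)
}

#' Instrument-strength diagnostics and the instrument-free exposure
#'
#' Ordinary least squares of the measured exposure on the GRS. Returns the
#' variance explained, the F-statistic `r2 * (n - 2) / (1 - r2)`, and the
#' instrument-free exposure: the OLS residual re-centred by adding back the
#' sample mean of the exposure, so that deficiency thresholds (25, 50
#' nmol/L) remain meaningful on the measured scale.
#'
#' @param grs numeric vector of scores.
#' @param vitd numeric vector of measured 25(OH)D, same length.
#' @return A list with `diagnostics` (list `r2`, `f_stat`, `n`) and
#'   `residuals` (the re-centred instrument-free exposure).
#' @export
instrument_diagnostics <- function(grs, vitd) {
  if (length(grs) != length(vitd)) stop("grs and vitd lengths differ")
  ok <- is.finite(grs) & is.finite(vitd)
  grs <- grs[ok]; vitd <- vitd[ok]
  n <- length(grs)
  if (n <= 2) stop("need more than 2 complete observations")
  if (var(grs) == 0) stop("GRS has zero variance")
  slope <- cov(grs, vitd) / var(grs)
  fitted <- mean(vitd) + slope * (grs - mean(grs))
  resid <- vitd - fitted
  r2 <- 1 - sum(resid^2) / sum((vitd - mean(vitd))^2)
  f_stat <- r2 * (n - 2) / (1 - r2)
  res <- rep(NA_real_, length(ok))
  res[ok] <- resid + mean(vitd)
  list(diagnostics = list(r2 = r2, f_stat = f_stat, n = n),
       residuals = res)
}

#' Remove a functional block (or a single variant) from a panel
#'
#' Leave-block-out sensitivity analysis: returns the panel without the
#' variants whose `block` label (or `variant_id`, enabling leave-one-out)
#' matches `block`. `"none"` returns the panel unchanged.
#'
#' @param panel a `variant_panel`.
#' @param block a block label or a variant id.
#' @return The reduced `variant_panel`.
#' @export
leave_block_out <- function(panel, block) {
  if (identical(block, "none")) return(panel)
  drop_idx <- panel$block == block | panel$variant_id == block
  out <- panel[!drop_idx, , drop = FALSE]
  if (!nrow(out))
    stop("excluding block '", block, "' would leave zero instruments")
  out
}
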
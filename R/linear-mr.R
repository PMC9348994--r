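#' Per-variant Wald ratio estimates
#'
#' `ratio_j = beta_outcome_j / beta_exposure_j`, with the first-order
#' delta-method SE `se_outcome_j / |beta_exposure_j|` (exposure-side
#' uncertainty is ignored at first order, the usual two-sample MR
#' convention for strong instruments).
#'
#' @param h a `harmonized_stats` data frame (only kept/flipped rows are
#'   used).
#' @return Data frame with `variant_id`, `ratio`, `se`.
#' @export
wald_ratios <- function(h) {
  k <- harmonized_kept(h)
  if (any(k$beta_exposure == 0))
    stop("zero exposure beta for: ",
         paste(k$variant_id[k$beta_exposure == 0], collapse = ", "))
  if (any(k$se_outcome <= 0)) stop("outcome SEs must be positive")
  data.frame(variant_id = k$variant_id,
             ratio = k$beta_outcome / k$beta_exposure,
             se = k$se_outcome / abs(k$beta_exposure),
             stringsAsFactors = FALSE)
}

new_mr_result <- function(method, estimate, se, p = NULL, q = NA_real_,
                          q_df = NA_integer_, q_p = NA_real_,
                          egger_intercept = NA_real_,
                          egger_intercept_p = NA_real_, n_used) {
  if (is.null(p)) p <- 2 * pnorm(-abs(estimate / se))
  structure(list(method = method, estimate = estimate, se = se,
                 ci_low = estimate - 1.96 * se,
                 ci_high = estimate + 1.96 * se, p = p,
                 cochran_q = q, q_df = q_df, q_p = q_p,
                 egger_intercept = egger_intercept,
                 egger_intercept_p = egger_intercept_p,
                 n_variants_used = n_used),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR estimate (%s): %.4g (95%% CI %.4g, %.4g), p = %.3g, J = %d\n",
              x$method, x$estimate, x$ci_low, x$ci_high, x$p,
              x$n_variants_used))
  if (!is.na(x$cochran_q))
    cat(sprintf("  Cochran Q = %.3g on %d df (p = %.3g)\n",
                x$cochran_q, x$q_df, x$q_p))
  if (!is.na(x$egger_intercept))
    cat(sprintf("  Egger intercept = %.4g (p = %.3g)\n",
                x$egger_intercept, x$egger_intercept_p))
  invisible(x)
}

ivw_core <- function(ratio, se) {
  w <- 1 / se^2
  est <- sum(w * ratio) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  q <- sum(w * (ratio - est)^2)
  list(est = est, se_fixed = se_fixed, q = q)
}

mr_ivw_re <- function(h) {
  wr <- wald_ratios(h)
  J <- nrow(wr)
  if (J < 1) stop("IVW needs at least 1 variant")
  if (J == 1)
    return(new_mr_result("ivw_re", wr$ratio, wr$se, q = 0, q_df = 0L,
                         q_p = NA_real_, n_used = 1L))
  core <- ivw_core(wr$ratio, wr$se)
  infl <- max(1, sqrt(core$q / (J - 1))) # multiplicative random effects
  new_mr_result("ivw_re", core$est, core$se_fixed * infl,
                q = core$q, q_df = J - 1L,
                q_p = pchisq(core$q, J - 1, lower.tail = FALSE), n_used = J)
}

mr_egger <- function(h) {
  k <- harmonized_kept(h)
  J <- nrow(k)
  if (J < 3) stop("MR-Egger needs at least 3 variants")
  # orient so all exposure betas are positive
  flip <- k$beta_exposure < 0
  bx <- ifelse(flip, -k$beta_exposure, k$beta_exposure)
  by <- ifelse(flip, -k$beta_outcome, k$beta_outcome)
  w <- 1 / k$se_outcome^2
  X <- cbind(1, bx)
  XtWX_inv <- chol2inv(chol(crossprod(X * sqrt(w))))
  beta <- drop(XtWX_inv %*% crossprod(X, w * by))
  resid <- by - drop(X %*% beta)
  q <- sum(w * resid^2)
  sigma <- sqrt(q / (J - 2))
  # multiplicative random effects, floored at 1 (no super-precision)
  ses <- sqrt(diag(XtWX_inv)) * max(1, sigma)
  est <- beta[2]; se <- ses[2]
  int <- beta[1]; int_se <- ses[1]
  new_mr_result("egger", est, se,
                p = 2 * pt(-abs(est / se), df = J - 2),
                q = q, q_df = J - 2L,
                q_p = pchisq(q, J - 2, lower.tail = FALSE),
                egger_intercept = int,
                egger_intercept_p = 2 * pt(-abs(int / int_se), df = J - 2),
                n_used = J)
}

weighted_median_point <- function(ratio, w) {
  o <- order(ratio)
  r <- ratio[o]; w <- w[o] / sum(w)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(r[1])
  if (cum[length(cum)] <= 0.5) return(r[length(r)])
  k <- max(which(cum < 0.5))
  r[k] + (r[k + 1] - r[k]) * (0.5 - cum[k]) / (cum[k + 1] - cum[k])
}

mode_bandwidth <- function(ratio, w, phi) {
  w <- w / sum(w)
  mu <- sum(w * ratio)
  s <- sqrt(sum(w * (ratio - mu)^2) * length(ratio) /
              max(length(ratio) - 1, 1))
  m <- mad(ratio)
  spread <- min(s, if (m > 0) m else s)
  if (spread <= 0) spread <- max(abs(ratio), 1e-8)
  phi * 0.9 * spread * length(ratio)^(-1 / 5)
}

weighted_mode_point <- function(ratio, w, phi = 1) {
  bw <- mode_bandwidth(ratio, w, phi)
  w <- w / sum(w)
  dens <- function(x)
    vapply(x, function(xi) sum(w * dnorm((xi - ratio) / bw)), numeric(1))
  grid <- seq(min(ratio) - 2 * bw, max(ratio) + 2 * bw, length.out = 512)
  x0 <- grid[which.max(dens(grid))]
  opt <- optimize(dens, lower = x0 - 2 * bw, upper = x0 + 2 * bw,
                  maximum = TRUE, tol = 1e-10)
  opt$maximum
}

boot_se <- function(h, point_fun, n_boot, seed) {
  k <- harmonized_kept(h)
  set.seed(seed)
  ests <- replicate(n_boot, {
    bx <- rnorm(nrow(k), k$beta_exposure, k$se_exposure)
    by <- rnorm(nrow(k), k$beta_outcome, k$se_outcome)
    bx[bx == 0] <- .Machine$double.eps
    point_fun(by / bx, (bx / k$se_outcome)^2)
  })
  sd(ests)
}

#' Two-sample MR estimators
#'
#' Pleiotropy-robust estimators computed from harmonized per-variant
#' summary statistics:
#' \describe{
#'   \item{ivw_re}{inverse-variance-weighted mean of the Wald ratios with
#'     multiplicative random-effects SE inflation
#'     `max(1, sqrt(Q / (J - 1)))` — the primary estimator.}
#'   \item{egger}{weighted regression of outcome betas on exposure betas
#'     with an intercept (weights `1 / se_outcome^2`, orientation fixed so
#'     all exposure betas are positive); the intercept tests directional
#'     pleiotropy.}
#'   \item{weighted_median}{50th percentile of the weight-standardized
#'     cumulative distribution of sorted ratios with linear interpolation;
#'     SE by seeded parametric bootstrap.}
#'   \item{weighted_mode}{maximizer of a weighted Gaussian-kernel density
#'     over the ratios, bandwidth `phi` times a modified Silverman rule;
#'     SE by seeded parametric bootstrap.}
#' }
#'
#' @param h a `harmonized_stats` data frame.
#' @param method one of `"ivw_re"`, `"egger"`, `"weighted_median"`,
#'   `"weighted_mode"`.
#' @param n_boot bootstrap replicates for median/mode SEs (default 1000).
#' @param phi bandwidth multiplier for the mode (default 1).
#' @param seed seed for the bootstrap.
#' @return An `mr_result` (estimate on the per-unit-exposure scale; see
#'   [or_per_10()] for the paper-style per-10-nmol/L odds ratio).
#' @export
mr_estimate <- function(h, method = c("ivw_re", "egger", "weighted_median",
                                      "weighted_mode"),
                        n_boot = 1000L, phi = 1, seed = 1L) {
  method <- match.arg(method)
  if (method == "ivw_re") return(mr_ivw_re(h))
  if (method == "egger") return(mr_egger(h))
  wr <- wald_ratios(h)
  if (nrow(wr) < 2) stop(method, " needs at least 2 variants")
  w <- 1 / wr$se^2
  if (all(w == 0)) stop("all weights are zero")
  if (method == "weighted_median") {
    est <- weighted_median_point(wr$ratio, w)
    se <- boot_se(h, function(r, wt) weighted_median_point(r, wt),
                  n_boot, seed)
  } else {
    est <- weighted_mode_point(wr$ratio, w, phi)
    se <- boot_se(h, function(r, wt) weighted_mode_point(r, wt, phi),
                  n_boot, seed)
  }
  new_mr_result(method, est, se, n_used = nrow(wr))
}

#' Report an MR estimate as an odds/hazard ratio per 10 nmol/L
#' @param x an `mr_result` whose estimate is per nmol/L.
#' @return Named vector `or`, `ci_low`, `ci_high`.
#' @export
or_per_10 <- function(x) {
  c(or = exp(10 * x$estimate),
    ci_low = exp(10 * x$ci_low), ci_high = exp(10 * x$ci_high))
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Global test: the observed residual sum of squares of each variant about
#' its leave-one-out IVW prediction, compared against `n_sim` parametric
#' simulations under the no-pleiotropy null. Outlier test: per-variant
#' simulated p-values, Bonferroni-corrected at `alpha`. The corrected
#' estimate is the random-effects IVW after removing flagged variants; the
#' distortion test compares the observed shift in the estimate against a
#' null of removing equally many variants at random.
#'
#' @param h a `harmonized_stats` data frame with >= 4 usable variants.
#' @param n_sim number of simulations (>= 100; default 1000).
#' @param seed RNG seed.
#' @param alpha outlier significance level before Bonferroni (default
#'   0.05).
#' @return List: `global_rss`, `global_p`, `outliers` (data frame with
#'   per-variant p and flag), `raw` and `corrected` `mr_result`s,
#'   `distortion_p`.
#' @export
mr_presso <- function(h, n_sim = 1000L, seed = 1L, alpha = 0.05) {
  k <- harmonized_kept(h)
  J <- nrow(k)
  if (J < 4) stop("MR-PRESSO needs at least 4 variants")
  if (n_sim < 100) stop("n_sim must be at least 100")
  bx <- k$beta_exposure; by <- k$beta_outcome
  sx <- k$se_exposure; sy <- k$se_outcome
  w <- 1 / sy^2

  loo_est <- function(bx, by, w) {
    t1 <- w * bx * by; t2 <- w * bx^2
    (sum(t1) - t1) / (sum(t2) - t2)
  }
  obs_loo <- loo_est(bx, by, w)
  rss_j <- w * (by - obs_loo * bx)^2
  rss_obs <- sum(rss_j)

  set.seed(seed)
  sim_rss <- matrix(NA_real_, n_sim, J)
  for (s in seq_len(n_sim)) {
    bx_s <- rnorm(J, bx, sx)
    by_s <- rnorm(J, obs_loo * bx, sy) # expected outcome under no pleiotropy
    loo_s <- loo_est(bx_s, by_s, w)
    sim_rss[s, ] <- w * (by_s - loo_s * bx_s)^2
  }
  global_p <- mean(rowSums(sim_rss) >= rss_obs)
  p_j <- colMeans(sweep(sim_rss, 2, rss_j, ">="))
  p_adj <- pmin(p_j * J, 1)
  flagged <- p_adj < alpha

  raw <- mr_ivw_re(k)
  corrected <- if (any(flagged) && sum(!flagged) >= 2)
    mr_ivw_re(k[!flagged, , drop = FALSE]) else raw

  distortion_p <- NA_real_
  if (any(flagged) && sum(!flagged) >= 2) {
    d_obs <- corrected$estimate - raw$estimate
    n_out <- sum(flagged)
    d_sim <- replicate(n_sim, {
      drop_idx <- sample.int(J, n_out)
      mr_ivw_re(k[-drop_idx, , drop = FALSE])$estimate - raw$estimate
    })
    distortion_p <- mean(abs(d_sim) >= abs(d_obs))
  }

  list(global_rss = rss_obs, global_p = global_p,
       outliers = data.frame(variant_id = k$variant_id, p = p_j,
                             p_bonferroni = p_adj, flagged = flagged,
                             stringsAsFactors = FALSE),
       raw = raw, corrected = corrected, distortion_p = distortion_p)
}

# --- fast within-cohort per-variant associations ---------------------------

# closed-form simple/multiple linear regression of y on x given a fixed
# covariate design; returns the coefficient of x and its SE
fast_lm_beta <- function(x, y, covar_mat = NULL) {
  X <- cbind(1, covar_mat, x)
  fit <- .lm.fit(X, y)
  p <- ncol(X)
  df <- length(y) - p
  sigma2 <- sum(fit$residuals^2) / df
  XtX_inv <- chol2inv(chol(crossprod(X)))
  c(beta = unname(fit$coefficients[p]), se = sqrt(sigma2 * XtX_inv[p, p]))
}

fast_logistic_beta <- function(x, y, covar_mat = NULL) {
  X <- cbind(1, covar_mat, x)
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(), control = list(maxit = 50)))
  p <- ncol(X)
  W <- fit$weights
  XtWX_inv <- chol2inv(chol(crossprod(X * sqrt(W))))
  c(beta = unname(fit$coefficients[p]), se = sqrt(XtWX_inv[p, p]))
}

covar_design <- function(cohort, covariates) {
  if (!length(covariates)) return(NULL)
  miss <- setdiff(covariates, names(cohort))
  if (length(miss)) stop("missing covariates: ", paste(miss, collapse = ", "))
  mm <- model.matrix(
    as.formula(paste("~", paste(covariates, collapse = " + "))),
    data = as.data.frame(cohort))
  mm[, -1, drop = FALSE]
}

#' Per-variant association statistics within a cohort
#'
#' For each panel variant: the covariate-adjusted linear-regression effect
#' of the dosage on 25(OH)D (exposure side) and the covariate-adjusted
#' effect on a binary event, by logistic regression (`family = "logistic"`)
#' or Cox regression on event/time (`family = "cox"`), giving
#' one-sample-derived summary statistics in `harmonized_stats` layout.
#'
#' @param cohort a `cohort_table` (or subset).
#' @param panel a `variant_panel`.
#' @param outcome `"dementia"` or `"stroke"`.
#' @param covariates covariate columns for both sides (default age and
#'   sex).
#' @param family outcome model, `"logistic"` (default) or `"cox"`.
#' @return A `harmonized_stats` data frame (all rows `kept`).
#' @export
variant_associations <- function(cohort, panel, outcome = "dementia",
                                 covariates = c("age", "sex"),
                                 family = c("logistic", "cox")) {
  family <- match.arg(family)
  D <- dosage_matrix(cohort)
  if (!all(panel$variant_id %in% colnames(D)))
    stop("cohort dosage columns do not cover the panel")
  D <- D[, panel$variant_id, drop = FALSE]
  C <- covar_design(cohort, covariates)
  y_event <- cohort[[paste0(outcome, "_event")]]
  if (is.null(y_event)) stop("cohort is missing column ", outcome, "_event")
  vit <- cohort$vitd
  res <- vapply(seq_len(ncol(D)), function(j) {
    ex <- fast_lm_beta(D[, j], vit, C)
    oc <- if (family == "logistic") fast_logistic_beta(D[, j], y_event, C)
    else {
      tm <- cohort[[paste0(outcome, "_time")]]
      X <- cbind(dosage = D[, j], C)
      f <- survival::coxph(survival::Surv(tm, y_event) ~ X, ties = "efron")
      co <- summary(f)$coefficients
      c(beta = unname(co[1, "coef"]), se = unname(co[1, "se(coef)"]))
    }
    c(ex, oc)
  }, numeric(4))
  h <- data.frame(
    variant_id = panel$variant_id,
    effect_allele = panel$effect_allele,
    other_allele = panel$other_allele,
    beta_exposure = res[1, ],
    se_exposure = res[2, ],
    eaf_exposure = panel$eaf,
    beta_outcome = res[3, ],
    se_outcome = res[4, ],
    eaf_outcome = panel$eaf,
    harmonization_action = "kept",
    stringsAsFactors = FALSE
  )
  class(h) <- c("harmonized_stats", "data.frame")
  h
}

#' Stratified linear MR across instrument-free 25(OH)D strata
#'
#' Stratifies individuals by the instrument-free (genetic-residual,
#' re-centred) 25(OH)D and, within each stratum, derives per-variant
#' exposure and outcome associations ([variant_associations()]) and applies
#' the two-sample estimators of [mr_estimate()]. Estimates are also
#' reported as odds ratios per 10 nmol/L higher 25(OH)D.
#'
#' @param cohort a `cohort_table`.
#' @param panel a `variant_panel`.
#' @param bounds interior stratum boundaries on the nmol/L scale (default
#'   `c(25, 50, 75)`, giving <25, 25-49.9, 50-74.9, >=75).
#' @param outcome,covariates,family passed to [variant_associations()].
#' @param methods estimators to run (default all four).
#' @param n_boot,seed bootstrap controls for median/mode.
#' @return List of class `stratified_mr`: one element per stratum with
#'   `stratum`, `n`, `n_events`, `results` (list of `mr_result`),
#'   `or_per_10` (matrix).
#' @export
stratified_mr <- function(cohort, panel, bounds = c(25, 50, 75),
                          outcome = "dementia",
                          covariates = c("age", "sex"),
                          family = c("logistic", "cox"),
                          methods = c("ivw_re", "egger", "weighted_median",
                                      "weighted_mode"),
                          n_boot = 500L, seed = 1L) {
  family <- match.arg(family)
  if (!length(bounds) || any(diff(bounds) <= 0))
    stop("bounds must be strictly increasing and non-empty")
  diag <- instrument_diagnostics(cohort$grs, cohort$vitd)
  breaks <- c(-Inf, bounds, Inf)
  g <- cut(diag$residuals, breaks = breaks, right = FALSE)
  if (any(table(g) == 0))
    stop("empty stratum: ", paste(levels(g)[table(g) == 0], collapse = ", "))
  ev_col <- paste0(outcome, "_event")
  out <- lapply(levels(g), function(lev) {
    sub <- cohort[!is.na(g) & g == lev, , drop = FALSE]
    if (sum(sub[[ev_col]]) == 0)
      stop("stratum ", lev, " has zero events")
    h <- variant_associations(sub, panel, outcome = outcome,
                              covariates = covariates, family = family)
    results <- lapply(methods, function(m)
      mr_estimate(h, m, n_boot = n_boot, seed = seed))
    names(results) <- methods
    ors <- t(vapply(results, or_per_10, numeric(3)))
    list(stratum = lev, n = nrow(sub), n_events = sum(sub[[ev_col]]),
         results = results, or_per_10 = ors)
  })
  names(out) <- levels(g)
  class(out) <- "stratified_mr"
  out
}
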
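#' Equal-size quantile stratification
#'
#' Assigns each observation to one of `k` strata of (near-)equal size by
#' the rank of the supplied instrument-free exposure. Stratum sizes differ
#' by at most 1 (the first `n %% k` strata take the extra member); ties are
#' broken by stable input order.
#'
#' @param x numeric vector (instrument-free 25(OH)D).
#' @param k number of strata (>= 3, and `n >= 10 * k`).
#' @return Integer vector of stratum indices 1..k, ordered so that stratum
#'   means of `x` increase.
#' @export
stratify_quantiles <- function(x, k) {
  n <- length(x)
  if (k < 3) stop("k must be at least 3")
  if (n < 10 * k) stop("need n >= 10 * k (n = ", n, ", k = ", k, ")")
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  ord <- order(x, seq_along(x)) # stable
  strat <- integer(n)
  strat[ord] <- rep.int(seq_len(k), times = sizes)
  strat
}

#' Localized average causal effect (LACE) per stratum
#'
#' Within each stratum: `beta_gx` is the covariate-adjusted linear
#' regression slope of measured 25(OH)D on the GRS and `beta_gy` the
#' covariate-adjusted GRS coefficient from a logistic (or Cox) model of the
#' event. The LACE is the ratio `beta_gy / beta_gx` with first-order
#' delta-method SE `se(beta_gy) / |beta_gx|` — the local derivative of the
#' causal log-odds dose-response at the stratum's mean exposure.
#'
#' A stratum is flagged as an outlier when its `beta_gx` falls outside the
#' 99.7% (3-sigma) prediction band around the precision-weighted pooled
#' `beta_gx`, operationalizing the check that the GRS-exposure association
#' is uniform across strata (extreme strata typically fail it, and the
#' primary curve is fitted with them removed).
#'
#' @param cohort a `cohort_table`.
#' @param strata integer stratum assignment from [stratify_quantiles()].
#' @param covariates covariate columns (default age, sex).
#' @param outcome `"dementia"` or `"stroke"`.
#' @param family `"logistic"` (default, odds scale) or `"cox"`.
#' @return A `stratum_lace` data frame ordered by `mean_exposure`:
#'   `index`, `n`, `n_events`, `mean_exposure`, `beta_gx`, `se_gx`,
#'   `beta_gy`, `se_gy`, `lace`, `se_lace`, `outlier_flag`.
#' @export
stratum_lace <- function(cohort, strata, covariates = c("age", "sex"),
                         outcome = "dementia",
                         family = c("logistic", "cox")) {
  family <- match.arg(family)
  ev_col <- paste0(outcome, "_event")
  tm_col <- paste0(outcome, "_time")
  if (!ev_col %in% names(cohort)) stop("missing column ", ev_col)
  ks <- sort(unique(strata))
  C_all <- covar_design(cohort, covariates)
  rows <- lapply(ks, function(kk) {
    idx <- which(strata == kk)
    sub_grs <- cohort$grs[idx]
    if (var(sub_grs) == 0) stop("stratum ", kk, " has zero GRS variance")
    ev <- cohort[[ev_col]][idx]
    if (sum(ev) == 0) stop("stratum ", kk, " has zero events")
    C <- if (is.null(C_all)) NULL else C_all[idx, , drop = FALSE]
    gx <- fast_lm_beta(sub_grs, cohort$vitd[idx], C)
    gy <- if (family == "logistic") fast_logistic_beta(sub_grs, ev, C)
    else {
      X <- cbind(grs = sub_grs, C)
      f <- survival::coxph(survival::Surv(cohort[[tm_col]][idx], ev) ~ X,
                           ties = "efron")
      co <- summary(f)$coefficients
      c(beta = co[1, "coef"], se = co[1, "se(coef)"])
    }
    data.frame(index = kk, n = length(idx), n_events = sum(ev),
               mean_exposure = mean(cohort$vitd[idx]),
               beta_gx = gx[["beta"]], se_gx = gx[["se"]],
               beta_gy = gy[["beta"]], se_gy = gy[["se"]],
               lace = gy[["beta"]] / gx[["beta"]],
               se_lace = gy[["se"]] / abs(gx[["beta"]]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mean_exposure), ]
  rownames(out) <- NULL
  # uniform-instrument check: 3-sigma prediction band around pooled beta_gx
  w <- 1 / out$se_gx^2
  pooled <- sum(w * out$beta_gx) / sum(w)
  se_pooled <- sqrt(1 / sum(w))
  out$outlier_flag <- abs(out$beta_gx - pooled) >
    3 * sqrt(out$se_gx^2 + se_pooled^2)
  class(out) <- c("stratum_lace", "data.frame")
  out
}

# fractional-polynomial bases. Powers label the effect function h(x):
# f_p(x) = x^p for p != 0, f_0(x) = ln x. The LACE estimates the derivative
# h'(x), so the design for the meta-regression uses f_p' and the curve
# itself integrates back to f_p analytically. Repeated powers use the
# ln-augmented convention (second basis term x^p * ln x).
fp_deriv_basis <- function(x, powers) {
  if (any(x <= 0)) stop("fractional polynomial needs positive exposures")
  if (length(powers) == 2 && powers[1] == powers[2]) {
    p <- powers[1]
    if (p == 0) cbind(1 / x, 2 * log(x) / x)
    else cbind(p * x^(p - 1), x^(p - 1) * (p * log(x) + 1))
  } else {
    vapply(powers, function(p) {
      if (p == 0) 1 / x else p * x^(p - 1)
    }, numeric(length(x)))
  }
}

fp_integral_basis <- function(x, powers) {
  if (any(x <= 0)) stop("fractional polynomial needs positive exposures")
  if (length(powers) == 2 && powers[1] == powers[2]) {
    p <- powers[1]
    if (p == 0) cbind(log(x), log(x)^2) else cbind(x^p, x^p * log(x))
  } else {
    vapply(powers, function(p) {
      if (p == 0) log(x) else x^p
    }, numeric(length(x)))
  }
}

fp_wls <- function(x, y, se, powers) {
  X <- fp_deriv_basis(x, powers)
  if (!is.matrix(X)) X <- matrix(X, ncol = length(powers))
  w <- 1 / se^2
  XtWX <- crossprod(X * sqrt(w))
  XtWy <- crossprod(X, w * y)
  cv <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
  if (is.null(cv)) return(NULL)
  theta <- drop(cv %*% XtWy)
  fitted <- drop(X %*% theta)
  ll <- sum(dnorm(y, fitted, se, log = TRUE))
  list(powers = powers, theta = theta, theta_cov = cv, loglik = ll,
       fitted = fitted)
}

fp_power_set <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Fit a fractional-polynomial dose-response to stratum LACE estimates
#'
#' Weighted (1/SE^2) meta-regression of the LACE estimates against the mean
#' 25(OH)D of each stratum, where the regression function is the derivative
#' of a fractional polynomial of degree 1 or 2 over the canonical power set
#' \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\} (power 0 = log; repeated powers use
#' the ln-augmented convention). Degree 1 scans all 8 powers, degree 2 all
#' 36 pairs; the best model maximizes the weighted likelihood, and degree 2
#' is retained only when it beats the best degree 1 at p < 0.05
#' (chi-square, 2 df). Flagged outlier strata are excluded when
#' `remove_outliers = TRUE` (the default, matching the primary analysis).
#'
#' @param laces a `stratum_lace` data frame.
#' @param degree 1, 2 or NULL (automatic selection, the default).
#' @param powers_set candidate powers.
#' @param remove_outliers drop strata with `outlier_flag` (default TRUE).
#' @param reference reference exposure for the odds-ratio curve, nmol/L
#'   (default 50).
#' @return An `effect_curve` object: `degree`, `powers`, `theta`,
#'   `theta_cov`, `reference`, `loglik`, `loglik_linear`, `support`
#'   (exposure range of the strata used), `scan` (per-candidate
#'   log-likelihood table), `laces_used`.
#' @export
fit_fp <- function(laces, degree = NULL, powers_set = fp_power_set,
                   remove_outliers = TRUE, reference = 50) {
  d <- as.data.frame(laces)
  if (remove_outliers && "outlier_flag" %in% names(d))
    d <- d[!d$outlier_flag, , drop = FALSE]
  want_deg <- if (is.null(degree)) 2L else as.integer(degree)
  if (nrow(d) < want_deg + 2)
    stop("need at least degree + 2 usable strata (have ", nrow(d), ")")
  x <- d$mean_exposure; y <- d$lace; se <- d$se_lace

  fits1 <- lapply(powers_set, function(p) fp_wls(x, y, se, p))
  fits1 <- fits1[!vapply(fits1, is.null, logical(1))]
  ll1 <- vapply(fits1, `[[`, numeric(1), "loglik")
  best1 <- fits1[[which.max(ll1)]]

  scan <- data.frame(
    degree = 1L,
    powers = vapply(fits1, function(f) paste(f$powers, collapse = ","),
                    character(1)),
    loglik = ll1, stringsAsFactors = FALSE)

  best2 <- NULL
  if (is.null(degree) || degree == 2L) {
    pairs <- cbind(rep(powers_set, each = length(powers_set)),
                   rep(powers_set, times = length(powers_set)))
    pairs <- pairs[pairs[, 1] <= pairs[, 2], , drop = FALSE]
    fits2 <- lapply(seq_len(nrow(pairs)),
                    function(i) fp_wls(x, y, se, pairs[i, ]))
    fits2 <- fits2[!vapply(fits2, is.null, logical(1))]
    if (length(fits2)) {
      ll2 <- vapply(fits2, `[[`, numeric(1), "loglik")
      best2 <- fits2[[which.max(ll2)]]
      scan <- rbind(scan, data.frame(
        degree = 2L,
        powers = vapply(fits2, function(f) paste(f$powers, collapse = ","),
                        character(1)),
        loglik = ll2, stringsAsFactors = FALSE))
    }
  }

  chosen <- if (!is.null(degree)) {
    if (degree == 1L) best1
    else if (!is.null(best2)) best2
    else stop("no degree-2 model could be fitted")
  } else if (!is.null(best2) &&
             pchisq(2 * (best2$loglik - best1$loglik), df = 2,
                    lower.tail = FALSE) < 0.05) best2 else best1

  lin <- fp_wls(x, y, se, 1)
  structure(list(
    degree = length(chosen$theta), powers = chosen$powers,
    theta = chosen$theta, theta_cov = chosen$theta_cov,
    reference = reference, loglik = chosen$loglik,
    loglik_best1 = best1$loglik, loglik_linear = lin$loglik,
    support = range(x), scan = scan, laces_used = d
  ), class = "effect_curve")
}

#' Construct an effect curve directly from coefficients
#'
#' Mostly for toy examples and tests; [fit_fp()] is the estimation route.
#' @param powers fractional-polynomial powers (h-function labels).
#' @param theta coefficient vector.
#' @param theta_cov coefficient covariance matrix.
#' @param reference reference exposure, nmol/L.
#' @param support numeric length-2 exposure range the curve is valid on.
#' @return An `effect_curve`.
#' @export
new_effect_curve <- function(powers, theta,
                             theta_cov = matrix(0, length(theta),
                                                length(theta)),
                             reference = 50, support = c(10, 240)) {
  structure(list(degree = length(theta), powers = powers, theta = theta,
                 theta_cov = theta_cov, reference = reference,
                 loglik = NA_real_, loglik_best1 = NA_real_,
                 loglik_linear = NA_real_, support = support,
                 scan = NULL, laces_used = NULL),
            class = "effect_curve")
}

#' Nonlinearity tests on the stratum LACE estimates
#'
#' \describe{
#'   \item{p_fp}{fractional-polynomial test: chi-square (1 df) comparison
#'     of the best degree-1 fractional polynomial against the linear
#'     (power 1, constant-derivative) model.}
#'   \item{p_quadratic}{Wald p-value of the slope in a precision-weighted
#'     meta-regression of the LACE on the stratum mean exposure (a nonzero
#'     slope means the derivative changes with exposure).}
#'   \item{p_q}{Cochran Q heterogeneity of the LACE about their pooled
#'     precision-weighted mean.}
#' }
#'
#' @param laces a `stratum_lace` data frame.
#' @param remove_outliers drop flagged strata first (default TRUE).
#' @return Named list `p_fp`, `p_quadratic`, `p_q` (plus `q`, `q_df`).
#' @export
test_nonlinearity <- function(laces, remove_outliers = TRUE) {
  d <- as.data.frame(laces)
  if (remove_outliers && "outlier_flag" %in% names(d))
    d <- d[!d$outlier_flag, , drop = FALSE]
  if (nrow(d) < 4) stop("need at least 4 usable strata")
  x <- d$mean_exposure; y <- d$lace; se <- d$se_lace
  w <- 1 / se^2

  fits1 <- lapply(fp_power_set, function(p) fp_wls(x, y, se, p))
  fits1 <- fits1[!vapply(fits1, is.null, logical(1))]
  ll1 <- max(vapply(fits1, `[[`, numeric(1), "loglik"))
  ll_lin <- fp_wls(x, y, se, 1)$loglik
  p_fp <- pchisq(max(2 * (ll1 - ll_lin), 0), df = 1, lower.tail = FALSE)

  # meta-regression of LACE on mean exposure (slope = curvature of h)
  X <- cbind(1, x)
  XtWX_inv <- chol2inv(chol(crossprod(X * sqrt(w))))
  beta <- drop(XtWX_inv %*% crossprod(X, w * y))
  se_slope <- sqrt(XtWX_inv[2, 2])
  p_quadratic <- 2 * pnorm(-abs(beta[2] / se_slope))

  pooled <- sum(w * y) / sum(w)
  q <- sum(w * (y - pooled)^2)
  p_q <- pchisq(q, df = nrow(d) - 1, lower.tail = FALSE)

  list(p_fp = p_fp, p_quadratic = p_quadratic, p_q = p_q,
       q = q, q_df = nrow(d) - 1L)
}

curve_delta_h <- function(curve, x) {
  Bx <- fp_integral_basis(x, curve$powers)
  if (!is.matrix(Bx)) Bx <- matrix(Bx, ncol = length(curve$theta))
  Br <- fp_integral_basis(curve$reference, curve$powers)
  if (!is.matrix(Br)) Br <- matrix(Br, ncol = length(curve$theta))
  sweep(Bx, 2, drop(Br))
}

theta_draws <- function(curve, n_draw, seed) {
  set.seed(seed)
  D <- length(curve$theta)
  Z <- matrix(rnorm(n_draw * D), D, n_draw)
  L <- tryCatch(chol(curve$theta_cov), error = function(e)
    matrix(0, D, D)) # degenerate covariance -> point mass
  curve$theta + t(L) %*% Z
}

#' Odds-ratio dose-response curve from a fitted effect curve
#'
#' The causal effect function difference `h(x) - h(reference)` is the
#' analytic integral of the fitted derivative basis, so
#' `OR(x) = exp(h(x) - h(reference))` with `OR(reference) = 1` exactly.
#' Confidence bands come from seeded multivariate-normal draws of the
#' coefficients using their covariance (percentile bands).
#'
#' @param curve an `effect_curve`.
#' @param x_grid exposure values, nmol/L (default 100 points over the
#'   curve support).
#' @param reference optional override of the curve's reference.
#' @param n_draw coefficient draws for the CI (default 10000).
#' @param seed RNG seed.
#' @param level confidence level (default 0.95).
#' @return Data frame `x`, `or`, `ci_low`, `ci_high`.
#' @export
effect_curve <- function(curve, x_grid = NULL, reference = NULL,
                         n_draw = 10000L, seed = 1L, level = 0.95) {
  if (!inherits(curve, "effect_curve")) stop("not an effect_curve")
  if (!is.null(reference)) curve$reference <- reference
  if (is.null(x_grid))
    x_grid <- seq(curve$support[1], curve$support[2], length.out = 100)
  if (any(x_grid <= 0)) stop("x outside support (must be positive)")
  B <- curve_delta_h(curve, x_grid)
  or <- exp(drop(B %*% curve$theta))
  TH <- theta_draws(curve, n_draw, seed)
  sims <- exp(B %*% TH)
  a <- (1 - level) / 2
  qs <- t(apply(sims, 1, quantile, probs = c(a, 1 - a), names = FALSE))
  data.frame(x = x_grid, or = or, ci_low = qs[, 1], ci_high = qs[, 2])
}

#' Odds ratio at a single exposure value
#' @inheritParams effect_curve
#' @param x exposure value, nmol/L.
#' @return Named vector `or`, `ci_low`, `ci_high`.
#' @export
or_at <- function(curve, x, reference = NULL, n_draw = 10000L, seed = 1L,
                  level = 0.95) {
  res <- effect_curve(curve, x_grid = x, reference = reference,
                      n_draw = n_draw, seed = seed, level = level)
  c(or = res$or[1], ci_low = res$ci_low[1], ci_high = res$ci_high[1])
}
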
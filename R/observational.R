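#' Default progressive-adjustment covariate sets
#'
#' Nested covariate ladders, each level a superset of the previous:
#' basic (age, sex, assessment center, ethnicity, month of measurement),
#' socioeconomic (+ education), lifestyle (+ BMI), sun behaviour
#' (+ time outdoors), illness (+ long-standing illness). Names refer to
#' columns of the synthetic `cohort_table`; pass your own named list to
#' [model_spec()] for other cohorts.
#' @return Named list of character vectors.
#' @export
default_adjustment_sets <- function() {
  basic <- c("age", "sex", "center", "ethnicity", "season_month")
  socioeconomic <- c(basic, "education")
  lifestyle <- c(socioeconomic, "bmi")
  sun <- c(lifestyle, "outdoor_time")
  illness <- c(sun, "illness")
  list(basic = basic, socioeconomic = socioeconomic, lifestyle = lifestyle,
       sun = sun, illness = illness)
}

#' Specify an observational model
#'
#' @param outcome outcome name. For `family = "cox"` this selects the
#'   `<outcome>_event` / `<outcome>_time` columns ("dementia", "stroke");
#'   for `family = "linear"` it is a column name (the `wmh` outcome is
#'   log-transformed before fitting, due to skewness).
#' @param family `"linear"` or `"cox"`.
#' @param adjustment_level one of the names of `covariate_sets`.
#' @param exposure_form `"per_10nmol"`, `"categorical"` or `"quadratic"`
#'   (informational; [fit_continuous()] always reports the per-10-nmol/L
#'   estimate and attaches the quadratic nonlinearity test).
#' @param weights use kinship weights `1 - kinship coefficient`
#'   (default TRUE).
#' @param covariate_sets named list of nested covariate vectors.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(outcome, family = c("linear", "cox"),
                       adjustment_level = "basic",
                       exposure_form = "per_10nmol",
                       weights = TRUE,
                       covariate_sets = default_adjustment_sets()) {
  family <- match.arg(family)
  if (!adjustment_level %in% names(covariate_sets))
    stop("unknown adjustment level: ", adjustment_level)
  structure(list(outcome = outcome, family = family,
                 adjustment_level = adjustment_level,
                 exposure_form = exposure_form, weights = weights,
                 covariate_sets = covariate_sets),
            class = "model_spec")
}

obs_frame <- function(cohort, spec) {
  covars <- spec$covariate_sets[[spec$adjustment_level]]
  miss <- setdiff(covars, names(cohort))
  if (length(miss))
    stop("cohort is missing covariate columns: ", paste(miss, collapse = ", "))
  d <- as.data.frame(cohort)
  d$.exposure10 <- d$vitd / 10
  d$.w <- if (isTRUE(spec$weights)) {
    if (!"kinship_weight" %in% names(d))
      stop("cohort is missing kinship_weight")
    d$kinship_weight
  } else rep(1, nrow(d))
  if ("season_month" %in% covars) d$season_month <- factor(d$season_month)
  if (spec$family == "cox") {
    ev <- paste0(spec$outcome, "_event"); tm <- paste0(spec$outcome, "_time")
    if (!all(c(ev, tm) %in% names(d)))
      stop("cohort is missing columns: ", ev, ", ", tm)
    if (any(d[[tm]] <= 0, na.rm = TRUE))
      stop("non-positive follow-up times")
    if (sum(d[[ev]], na.rm = TRUE) == 0)
      stop("outcome '", spec$outcome, "' has zero events")
    d$.time <- d[[tm]]; d$.event <- d[[ev]]
  } else {
    if (!spec$outcome %in% names(d))
      stop("cohort is missing outcome column: ", spec$outcome)
    d$.y <- if (spec$outcome == "wmh") log(d[[spec$outcome]])
            else d[[spec$outcome]]
  }
  list(data = d, covars = covars)
}

#' Fit the continuous (per 10 nmol/L) observational model
#'
#' Linear regression for brain-volume outcomes (white matter hyperintensity
#' is log-transformed first) or a Cox proportional-hazards model (Efron tie
#' handling) for dementia/stroke incidence, weighted by
#' `1 - kinship coefficient`, with the progressive covariate set chosen in
#' the spec. The nonlinearity p-value comes from a likelihood-ratio test of
#' an added quadratic 25(OH)D term; Cox fits also attach the
#' Schoenfeld-residual proportional-hazards p-value for the exposure term.
#'
#' @param cohort a `cohort_table`.
#' @param spec a [model_spec()].
#' @return A list of class `assoc_result`: `estimate` (beta or log-HR per
#'   10 nmol/L), `ci_low`, `ci_high`, `p_trend`, `p_nonlinear`, `n_used`,
#'   `hr` (Cox only), `p_schoenfeld` (Cox only).
#' @export
fit_continuous <- function(cohort, spec) {
  fr <- obs_frame(cohort, spec)
  d <- fr$data
  rhs <- paste(c(".exposure10", fr$covars), collapse = " + ")
  rhs2 <- paste(c(".exposure10", "I(.exposure10^2)", fr$covars),
                collapse = " + ")
  if (spec$family == "cox") {
    f1 <- as.formula(paste("survival::Surv(.time, .event) ~", rhs))
    f2 <- as.formula(paste("survival::Surv(.time, .event) ~", rhs2))
    m1 <- survival::coxph(f1, data = d, weights = d$.w, ties = "efron")
    m2 <- survival::coxph(f2, data = d, weights = d$.w, ties = "efron")
    co <- summary(m1)$coefficients
    est <- co[".exposure10", "coef"]
    se <- co[".exposure10", "se(coef)"]
    p_trend <- co[".exposure10", "Pr(>|z|)"]
    lrt <- 2 * (m2$loglik[2] - m1$loglik[2])
    p_nonlinear <- pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
    zph <- tryCatch(survival::cox.zph(m1), error = function(e) NULL)
    p_sch <- if (!is.null(zph)) unname(zph$table[".exposure10", "p"])
             else NA_real_
    res <- list(estimate = est, se = se, hr = exp(est),
                ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
                p_trend = p_trend, p_nonlinear = p_nonlinear,
                p_schoenfeld = p_sch, n_used = m1$n, family = "cox",
                outcome = spec$outcome)
  } else {
    f1 <- as.formula(paste(".y ~", rhs))
    f2 <- as.formula(paste(".y ~", rhs2))
    m1 <- lm(f1, data = d, weights = d$.w)
    m2 <- lm(f2, data = d, weights = d$.w)
    co <- summary(m1)$coefficients
    est <- co[".exposure10", "Estimate"]
    se <- co[".exposure10", "Std. Error"]
    p_trend <- co[".exposure10", "Pr(>|t|)"]
    p_nonlinear <- anova(m1, m2)[2, "Pr(>F)"]
    res <- list(estimate = est, se = se,
                ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
                p_trend = p_trend, p_nonlinear = p_nonlinear,
                n_used = nrow(m1$model), family = "linear",
                outcome = spec$outcome)
  }
  structure(res, class = "assoc_result")
}

#' Fit the categorical 25(OH)D observational model
#'
#' Groups 25(OH)D into clinical bins (default <25, 25-49.9, 50-74.9,
#' 75-99.9, 100-124.9, 125-240 nmol/L) with 50-74.9 nmol/L as the omitted
#' reference, and reports the per-bin estimate (HR or beta difference vs
#' reference; the reference row is exactly 1 / 0).
#'
#' @param cohort a `cohort_table`.
#' @param spec a [model_spec()].
#' @param bins increasing break points covering the exposure support
#'   (default `c(10, 25, 50, 75, 100, 125, 240)`).
#' @param reference_bin index of the reference interval (default the
#'   50-74.9 bin).
#' @return Data frame, one row per bin: `bin`, `n`, `estimate`, `ci_low`,
#'   `ci_high`, `p` (`estimate` is HR for Cox, beta for linear;
#'   `log_estimate` carries the log-HR).
#' @export
fit_categorical <- function(cohort, spec,
                            bins = c(10, 25, 50, 75, 100, 125, 240),
                            reference_bin = 3L) {
  fr <- obs_frame(cohort, spec)
  d <- fr$data
  v <- d$vitd
  if (any(v < bins[1] | v > bins[length(bins)], na.rm = TRUE))
    stop("bins do not cover the exposure support [",
         round(min(v, na.rm = TRUE), 1), ", ",
         round(max(v, na.rm = TRUE), 1), "]")
  g <- cut(v, breaks = bins, right = FALSE, include.lowest = TRUE)
  if (any(table(g) == 0)) stop("empty 25(OH)D bin: ",
                               paste(levels(g)[table(g) == 0], collapse = ", "))
  lev <- levels(g)
  d$.bin <- relevel(g, ref = lev[reference_bin])
  rhs <- paste(c(".bin", fr$covars), collapse = " + ")
  is_cox <- spec$family == "cox"
  if (is_cox) {
    f <- as.formula(paste("survival::Surv(.time, .event) ~", rhs))
    m <- survival::coxph(f, data = d, weights = d$.w, ties = "efron")
    co <- summary(m)$coefficients
    est_col <- "coef"; se_col <- "se(coef)"; p_col <- "Pr(>|z|)"
  } else {
    f <- as.formula(paste(".y ~", rhs))
    m <- lm(f, data = d, weights = d$.w)
    co <- summary(m)$coefficients
    est_col <- "Estimate"; se_col <- "Std. Error"; p_col <- ncol(co)
  }
  out <- do.call(rbind, lapply(lev, function(b) {
    if (b == lev[reference_bin])
      return(data.frame(bin = b, n = sum(g == b, na.rm = TRUE),
                        log_estimate = 0,
                        estimate = if (is_cox) 1 else 0,
                        ci_low = NA_real_, ci_high = NA_real_, p = NA_real_))
    rn <- paste0(".bin", b)
    est <- co[rn, est_col]; se <- co[rn, se_col]
    data.frame(bin = b, n = sum(g == b, na.rm = TRUE),
               log_estimate = est,
               estimate = if (is_cox) exp(est) else est,
               ci_low = if (is_cox) exp(est - 1.96 * se) else est - 1.96 * se,
               ci_high = if (is_cox) exp(est + 1.96 * se) else est + 1.96 * se,
               p = co[rn, p_col])
  }))
  rownames(out) <- NULL
  out
}

#' Likelihood-ratio interaction tests
#'
#' Two-way tests add an exposure-by-modifier product term for each modifier;
#' three-way tests (for a pair of modifiers) add the triple product on top
#' of all two-way terms. Continuous modifiers (age, BMI) enter as continuous,
#' categorical modifiers (sex, ethnicity) as factors, as supplied in the
#' cohort.
#'
#' @param cohort a `cohort_table`.
#' @param spec a [model_spec()].
#' @param modifiers character vector of modifier columns; for
#'   `order = 3` exactly two modifiers.
#' @param order 2 (default) or 3.
#' @return Named vector of LRT p-values (one per modifier for `order = 2`;
#'   a single value for `order = 3`).
#' @export
test_interaction <- function(cohort, spec, modifiers, order = 2L) {
  fr <- obs_frame(cohort, spec)
  d <- fr$data
  for (m in modifiers) {
    if (!m %in% names(d)) stop("modifier not found: ", m)
    if (length(unique(d[[m]][!is.na(d[[m]])])) < 2L)
      stop("modifier '", m, "' has a single level")
  }
  covars <- unique(c(fr$covars, modifiers))
  base_rhs <- paste(c(".exposure10", covars), collapse = " + ")
  lrt_p <- function(rhs0, rhs1, df) {
    if (spec$family == "cox") {
      m0 <- survival::coxph(as.formula(
        paste("survival::Surv(.time, .event) ~", rhs0)),
        data = d, weights = d$.w, ties = "efron")
      m1 <- survival::coxph(as.formula(
        paste("survival::Surv(.time, .event) ~", rhs1)),
        data = d, weights = d$.w, ties = "efron")
      stat <- 2 * (m1$loglik[2] - m0$loglik[2])
    } else {
      m0 <- lm(as.formula(paste(".y ~", rhs0)), data = d, weights = d$.w)
      m1 <- lm(as.formula(paste(".y ~", rhs1)), data = d, weights = d$.w)
      stat <- as.numeric(2 * (logLik(m1) - logLik(m0)))
    }
    pchisq(max(stat, 0), df = df, lower.tail = FALSE)
  }
  n_lev <- function(m) {
    x <- d[[m]]
    if (is.factor(x) || is.character(x)) length(unique(x[!is.na(x)])) - 1L
    else 1L
  }
  if (order == 2L) {
    p <- vapply(modifiers, function(m) {
      lrt_p(base_rhs, paste(base_rhs, "+ .exposure10:", m), n_lev(m))
    }, numeric(1))
    return(p)
  }
  if (order == 3L) {
    if (length(modifiers) != 2L)
      stop("three-way test needs exactly two modifiers")
    m1n <- modifiers[1]; m2n <- modifiers[2]
    two <- paste(base_rhs,
                 "+ .exposure10:", m1n, "+ .exposure10:", m2n,
                 "+", m1n, ":", m2n)
    three <- paste(two, "+ .exposure10:", m1n, ":", m2n)
    p <- lrt_p(two, three, n_lev(m1n) * n_lev(m2n))
    return(c(three_way = p))
  }
  stop("order must be 2 or 3")
}

#' Pre-fit exclusion filters
#'
#' `filter_exposure_limits()` sets 25(OH)D values outside the assay's
#' reportable limits to missing (default \[10, 375\] nmol/L).
#' `filter_volume_outliers()` drops rows more than `n_sd` SDs from the mean
#' of any listed brain-volume column. Both record counts in attributes
#' (`n_set_missing`, `n_excluded`).
#'
#' @param cohort a `cohort_table`.
#' @param lower,upper reportable limits, nmol/L.
#' @param columns brain-volume columns to screen.
#' @param n_sd outlier threshold in SD units (default 3).
#' @return The filtered cohort.
#' @export
filter_exposure_limits <- function(cohort, lower = 10, upper = 375) {
  bad <- !is.na(cohort$vitd) & (cohort$vitd < lower | cohort$vitd > upper)
  cohort$vitd[bad] <- NA_real_
  attr(cohort, "n_set_missing") <- sum(bad)
  cohort
}

#' @rdname filter_exposure_limits
#' @export
filter_volume_outliers <- function(cohort,
                                   columns = c("total_volume", "gray_volume",
                                               "white_volume",
                                               "hippocampal_volume"),
                                   n_sd = 3) {
  columns <- intersect(columns, names(cohort))
  out <- rep(FALSE, nrow(cohort))
  for (col in columns) {
    x <- cohort[[col]]
    mu <- mean(x, na.rm = TRUE); s <- sd(x, na.rm = TRUE)
    out <- out | (!is.na(x) & abs(x - mu) > n_sd * s)
  }
  res <- cohort[!out, , drop = FALSE]
  attr(res, "n_excluded") <- sum(out)
  res
}
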
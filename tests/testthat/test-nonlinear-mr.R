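test_that("quantile stratification yields equal strata in input order", {
  set.seed(51)
  x <- rnorm(4000)
  s <- stratify_quantiles(x, 40)
  expect_true(all(table(s) == 100))
  means <- tapply(x, s, mean)
  expect_true(all(diff(means) > 0))
  # n not divisible by k: sizes differ by at most one, extras first
  s2 <- stratify_quantiles(rnorm(4001), 40)
  tab <- as.integer(table(s2))
  expect_setequal(unique(tab), c(100L, 101L))
  expect_equal(sum(tab == 101L), 1L)
  expect_equal(tab[1], 101L)
  expect_error(stratify_quantiles(rnorm(100), 11), "n >= 10")
  expect_error(stratify_quantiles(rnorm(100), 2), "at least 3")
})

test_that("ties are broken by stable input order", {
  x <- rep(c(1, 2), each = 20)
  s <- stratify_quantiles(x, 4)
  expect_equal(s, rep(1:4, each = 10))
})

test_that("stratum LACE is invariant to shifting the stratifying residual", {
  fx <- default_cohort(n = 6000L, seed = 53L, baseline_hazard = 5e-3)
  d <- instrument_diagnostics(fx$cohort$grs, fx$cohort$vitd)
  s1 <- stratify_quantiles(d$residuals, 5)
  s2 <- stratify_quantiles(d$residuals + 100, 5)
  expect_equal(s1, s2)
  l1 <- stratum_lace(fx$cohort, s1)
  l2 <- stratum_lace(fx$cohort, s2)
  expect_equal(l1$lace, l2$lace, tolerance = 1e-12)
})

test_that("a globally null outcome yields null LACE in every stratum", {
  fx <- default_cohort(n = 30000L, seed = 59L,
                       causal_slope_below_knot = 0,
                       causal_slope_above_knot = 0,
                       confounder_effect_outcome = 0,
                       baseline_hazard = 5e-3)
  d <- instrument_diagnostics(fx$cohort$grs, fx$cohort$vitd)
  laces <- stratum_lace(fx$cohort, stratify_quantiles(d$residuals, 10))
  w <- 1 / laces$se_lace^2
  pooled <- sum(w * laces$lace) / sum(w)
  se_pooled <- sqrt(1 / sum(w))
  expect_lt(abs(pooled / se_pooled), 1.96)
})

test_that("a strictly linear causal slope is recovered by the pooled LACE", {
  s_true <- -0.01
  fx <- default_cohort(n = 100000L, seed = 61L,
                       causal_slope_below_knot = s_true,
                       causal_slope_above_knot = s_true,
                       baseline_hazard = 5e-3)
  d <- instrument_diagnostics(fx$cohort$grs, fx$cohort$vitd)
  laces <- stratum_lace(fx$cohort, stratify_quantiles(d$residuals, 20))
  keep <- !laces$outlier_flag
  w <- 1 / laces$se_lace[keep]^2
  pooled <- sum(w * laces$lace[keep]) / sum(w)
  se_pooled <- sqrt(1 / sum(w))
  expect_lt(abs(pooled - s_true), 3 * se_pooled)
})

test_that("zero-event strata are refused", {
  fx <- default_cohort(n = 2000L, seed = 67L, baseline_hazard = 1e-5)
  d <- instrument_diagnostics(fx$cohort$grs, fx$cohort$vitd)
  expect_error(stratum_lace(fx$cohort, stratify_quantiles(d$residuals, 20)),
               "zero events")
})

test_that("constant LACE selects the linear effect function (power 1)", {
  hits <- 0L
  for (s in 1:20) {
    laces <- make_laces(s, dfun = function(x) rep(0.02, length(x)))
    cv <- fit_fp(laces, degree = 1)
    hits <- hits + (length(cv$powers) == 1 && cv$powers == 1)
  }
  expect_gt(hits, 10) # majority of seeds
  laces <- make_laces(1, se = rep(1e-4, 20))
  cv <- fit_fp(laces, degree = 1)
  expect_equal(cv$powers, 1)
  expect_equal(cv$theta, 0.02, tolerance = 1e-2)
})

test_that("a log effect function is recovered with its derivative x^-1", {
  theta <- 0.8 # h(x) = theta * ln x, so the LACE profile is theta / x
  hits <- 0L; recovered <- 0L
  for (s in 1:20) {
    laces <- make_laces(100 + s, dfun = function(x) theta / x,
                        se = rep(0.003, 20))
    cv <- fit_fp(laces, degree = 1)
    if (length(cv$powers) == 1 && cv$powers == 0) {
      hits <- hits + 1L
      se_theta <- sqrt(cv$theta_cov[1, 1])
      recovered <- recovered + (abs(cv$theta - theta) < 2 * se_theta)
    }
  }
  expect_gt(hits, 10)
  expect_gt(recovered / max(hits, 1), 0.8)
})

test_that("fractional-polynomial WLS equals the normal-equations solve", {
  laces <- make_laces(3, x = c(15, 25, 40, 55, 70, 90),
                      dfun = function(x) 0.5 / x, se = rep(0.004, 6))
  cv <- fit_fp(laces, degree = 2, powers_set = c(0, 1))
  X <- cbind(1 / laces$mean_exposure, 1) # derivatives of ln x and x
  Xb <- vitdmr:::fp_deriv_basis(laces$mean_exposure, cv$powers)
  w <- 1 / laces$se_lace^2
  beta <- solve(t(Xb) %*% (w * Xb), t(Xb) %*% (w * laces$lace))
  expect_equal(cv$theta, drop(beta), tolerance = 1e-10)
  expect_error(fit_fp(laces[1:2, ], degree = 2), "at least")
})

test_that("identical LACE with equal SEs give zero heterogeneity", {
  laces <- make_laces(1, se = rep(0.005, 20))
  laces$lace <- rep(0.02, 20)
  nt <- test_nonlinearity(laces)
  expect_equal(nt$q, 0, tolerance = 1e-12)
  expect_equal(nt$p_q, 1)
})

test_that("degree-2 models are only retained when they earn it", {
  # pure linear truth: automatic selection should stay at degree 1
  deg <- vapply(1:10, function(s) {
    fit_fp(make_laces(200 + s), degree = NULL)$degree
  }, numeric(1))
  expect_gt(mean(deg == 1), 0.5)
})

test_that("the effect curve is anchored at the reference and exponentiates h", {
  # theta = 0: flat curve at OR 1
  cv0 <- new_effect_curve(powers = 1, theta = 0)
  g <- effect_curve(cv0, x_grid = c(20, 50, 100), n_draw = 500)
  expect_equal(g$or, rep(1, 3))
  # known linear curve: OR(x) = exp(theta (x - ref)) exactly
  th <- -0.02
  cv1 <- new_effect_curve(powers = 1, theta = th, reference = 50)
  g1 <- effect_curve(cv1, x_grid = c(25, 50, 75), n_draw = 500)
  expect_equal(g1$or, exp(th * (c(25, 50, 75) - 50)), tolerance = 1e-12)
  expect_equal(or_at(cv1, 50)[["or"]], 1)
  # CI bands contain the point curve
  cv2 <- new_effect_curve(powers = 1, theta = th,
                          theta_cov = matrix(4e-6, 1, 1), reference = 50)
  g2 <- effect_curve(cv2, x_grid = seq(15, 90, by = 5), seed = 2)
  expect_true(all(g2$ci_low <= g2$or + 1e-12))
  expect_true(all(g2$ci_high >= g2$or - 1e-12))
  expect_error(effect_curve(cv2, x_grid = c(-5, 50)), "support")
})

test_that("outlier strata flagging responds to a deviant first-stage slope", {
  laces <- make_laces(5, se = rep(0.004, 20))
  laces$beta_gx <- 1; laces$se_gx <- 0.01
  laces$beta_gx[1] <- 0.5 # far outside the 3-sigma band
  w <- 1 / laces$se_gx^2
  pooled <- sum(w * laces$beta_gx) / sum(w)
  se_pooled <- sqrt(1 / sum(w))
  flag <- abs(laces$beta_gx - pooled) >
    3 * sqrt(laces$se_gx^2 + se_pooled^2)
  expect_true(flag[1])
  expect_false(any(flag[-1]))
})
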
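test_that("Wald ratios follow the delta-method formulas", {
  h <- h_from_vectors(bx = c(1, 2), by = c(0.5, 1), sy = c(0.1, 0.2))
  wr <- wald_ratios(h)
  expect_equal(wr$ratio, c(0.5, 0.5))
  expect_equal(wr$se, c(0.1, 0.1))
  h0 <- h_from_vectors(bx = c(1, 0), by = c(0.5, 1))
  expect_error(wald_ratios(h0), "zero exposure beta")
})

test_that("first-order ratio SE agrees with Monte Carlo for strong instruments", {
  bx <- 1; sx <- 0.05; by <- 0.4; sy <- 0.08 # |bx|/sx = 20
  set.seed(101)
  draws <- rnorm(1e5, by, sy) / rnorm(1e5, bx, sx)
  h <- h_from_vectors(bx, by, sx, sy)
  se_delta <- wald_ratios(h)$se
  expect_lt(abs(se_delta - sd(draws)) / sd(draws), 0.10)
})

test_that("identical ratios collapse every estimator to the consensus", {
  h <- h_from_vectors(bx = c(1, 2, 4, 0.5, 3), by = c(0.5, 1, 2, 0.25, 1.5),
                      sy = c(0.1, 0.1, 0.2, 0.05, 0.3))
  for (m in c("ivw_re", "egger", "weighted_median", "weighted_mode")) {
    r <- mr_estimate(h, m, n_boot = 50)
    expect_equal(r$estimate, 0.5, tolerance = 1e-6)
  }
  expect_equal(mr_estimate(h, "ivw_re")$cochran_q, 0, tolerance = 1e-12)
})

test_that("a single variant IVW equals its Wald ratio", {
  h <- h_from_vectors(bx = 2, by = 1, sy = 0.2)
  r <- mr_estimate(h, "ivw_re")
  expect_equal(r$estimate, 0.5)
  expect_equal(r$se, 0.1)
})

test_that("IVW and Egger match brute-force weighted least squares", {
  h <- make_toy_harmonized(5, J = 5, theta = 0.08)
  k <- harmonized_kept(h)
  w <- 1 / k$se_outcome^2

  # IVW: no-intercept WLS of outcome betas on exposure betas
  X <- matrix(k$beta_exposure, ncol = 1)
  beta_wls <- solve(t(X) %*% (w * X), t(X) %*% (w * k$beta_outcome))
  ivw <- mr_estimate(h, "ivw_re")
  expect_equal(ivw$estimate, drop(beta_wls), tolerance = 1e-8)

  # Egger: WLS with intercept (same orientation: all bx > 0 here)
  X2 <- cbind(1, k$beta_exposure)
  beta2 <- solve(t(X2) %*% (w * X2), t(X2) %*% (w * k$beta_outcome))
  egger <- mr_estimate(h, "egger")
  expect_equal(egger$estimate, beta2[2], tolerance = 1e-8)
  expect_equal(egger$egger_intercept, beta2[1], tolerance = 1e-8)

  # random-effects Q and df bookkeeping
  expect_equal(ivw$q_df, 4L)
  expect_equal(ivw$q_p, pchisq(ivw$cochran_q, 4, lower.tail = FALSE))
})

test_that("the weighted median matches a fine-grid crossing search", {
  h <- make_toy_harmonized(11, J = 9, theta = 0.05)
  wr <- wald_ratios(h)
  w <- (1 / wr$se^2)
  est <- mr_estimate(h, "weighted_median", n_boot = 50)$estimate
  # oracle: dense grid over the interpolated weighted CDF
  o <- order(wr$ratio)
  r <- wr$ratio[o]; ws <- w[o] / sum(w)
  cum <- cumsum(ws) - ws / 2
  grid <- seq(min(r), max(r), length.out = 200001)
  cdf <- approx(r, cum, xout = grid, rule = 2)$y
  oracle <- grid[which.min(abs(cdf - 0.5))]
  expect_equal(est, oracle, tolerance = 1e-4)
  expect_gte(est, min(r)); expect_lte(est, max(r))
})

test_that("IVW with equal SEs is the unweighted mean of ratios", {
  h <- h_from_vectors(bx = rep(1, 4), by = c(0.1, 0.2, 0.3, 0.6),
                      sy = rep(0.1, 4))
  expect_equal(mr_estimate(h, "ivw_re")$estimate, mean(c(0.1, 0.2, 0.3, 0.6)),
               tolerance = 1e-12)
})

test_that("median and mode are invariant to variant ordering", {
  h <- make_toy_harmonized(13, J = 11, theta = 0.05)
  perm <- h[sample(nrow(h)), ]
  class(perm) <- class(h)
  for (m in c("weighted_median", "weighted_mode")) {
    expect_equal(mr_estimate(h, m, n_boot = 20)$estimate,
                 mr_estimate(perm, m, n_boot = 20)$estimate,
                 tolerance = 1e-8)
  }
})

test_that("estimators are equivariant under exposure rescaling", {
  h <- make_toy_harmonized(17, J = 8, theta = 0.05)
  h10 <- h
  h10$beta_exposure <- h$beta_exposure / 10 # nmol/L -> per 10 nmol/L units
  h10$se_exposure <- h$se_exposure / 10
  for (m in c("ivw_re", "egger", "weighted_median")) {
    expect_equal(mr_estimate(h10, m, n_boot = 20, seed = 2)$estimate,
                 10 * mr_estimate(h, m, n_boot = 20, seed = 2)$estimate,
                 tolerance = 1e-8)
  }
  expect_equal(mr_estimate(h10, "weighted_mode", n_boot = 20, seed = 2)$estimate,
               10 * mr_estimate(h, "weighted_mode", n_boot = 20, seed = 2)$estimate,
               tolerance = 1e-5)
})

test_that("Egger with a null intercept reduces to fixed-effect IVW", {
  h <- make_toy_harmonized(19, J = 6, theta = 0.05)
  k <- harmonized_kept(h)
  w <- 1 / k$se_outcome^2
  # constrain the intercept to zero: WLS through the origin == fixed IVW
  slope0 <- sum(w * k$beta_exposure * k$beta_outcome) /
    sum(w * k$beta_exposure^2)
  expect_equal(mr_estimate(h, "ivw_re")$estimate, slope0, tolerance = 1e-8)
})

test_that("MR result intervals and guards are consistent", {
  h <- make_toy_harmonized(23, J = 10, theta = 0.05)
  r <- mr_estimate(h, "ivw_re")
  expect_equal(r$ci_low, r$estimate - 1.96 * r$se)
  expect_equal(r$ci_high, r$estimate + 1.96 * r$se)
  expect_equal(r$q_df, r$n_variants_used - 1L)
  h2 <- make_toy_harmonized(23, J = 2)
  expect_error(mr_estimate(h2, "egger"), "at least 3")
  h3 <- make_toy_harmonized(23, J = 3)
  expect_error(mr_presso(h3), "at least 4")
})

test_that("MR-PRESSO flags a displaced variant and corrects toward truth", {
  h <- make_toy_harmonized(29, J = 35, theta = 0.05, displace_se = 10)
  pr <- mr_presso(h, n_sim = 1000, seed = 3)
  expect_true(pr$outliers$flagged[7])
  expect_lt(pr$global_p, 0.05)
  expect_lt(abs(pr$corrected$estimate - 0.05), abs(pr$raw$estimate - 0.05))
  # clean stats: global test retains the null
  h0 <- make_toy_harmonized(47, J = 35, theta = 0.05)
  pr0 <- mr_presso(h0, n_sim = 500, seed = 3)
  expect_gt(pr0$global_p, 0.05)
  expect_equal(sum(pr0$outliers$flagged), 0)
})

test_that("stratified MR guards bounds, strata and events", {
  fx <- default_cohort(n = 5000L, seed = 37L, baseline_hazard = 5e-3)
  expect_error(stratified_mr(fx$cohort, fx$panel, bounds = numeric(0)),
               "bounds")
  expect_error(stratified_mr(fx$cohort, fx$panel, bounds = c(50, 25)),
               "bounds")
  expect_error(stratified_mr(fx$cohort, fx$panel, bounds = c(25, 50, 239)),
               "empty stratum|zero events")
  sm <- stratified_mr(fx$cohort, fx$panel, bounds = c(40, 60),
                      methods = "ivw_re", n_boot = 50)
  expect_length(sm, 3)
  expect_true(all(vapply(sm, function(x) x$n_events > 0, logical(1))))
  ors <- vapply(sm, function(x) x$or_per_10["ivw_re", "or"], numeric(1))
  expect_true(all(is.finite(ors)))
})
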
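sumstats_df <- function(id, ea, oa, eaf, beta, se, pval) {
  data.frame(variant_id = id, effect_allele = ea, other_allele = oa,
             eaf = eaf, beta = beta, se = se, pval = pval,
             stringsAsFactors = FALSE)
}

test_that("instrument selection applies MAF, replication and sign filters", {
  # hand enumeration: v1 kept; v2 wrong sign; v3 low MAF; v4 replication
  # p >= 0.05; v5 kept
  disc <- sumstats_df(paste0("v", 1:5), "A", "G",
                      eaf = c(0.3, 0.3, 0.3, 0.3, 0.4),
                      beta = c(1, 1, 1, 1, -2), se = 0.1, pval = 1e-8)
  repl <- sumstats_df(paste0("v", 1:5), "A", "G",
                      eaf = c(0.30, 0.30, 0.03, 0.30, 0.40),
                      beta = c(0.9, -1, 0.8, 0.7, -1.8), se = 0.1,
                      pval = c(0.001, 0.001, 0.001, 0.2, 0.001))
  panel <- select_instruments(disc, repl)
  expect_setequal(panel$variant_id, c("v1", "v5"))
  # weights come from the replication source
  expect_equal(panel$weight_exposure[panel$variant_id == "v1"], 0.9)
  expect_equal(panel$weight_exposure[panel$variant_id == "v5"], -1.8)
  expect_error(select_instruments(disc[0, ], repl), "shared")
})

test_that("harmonization flips, drops and records actions correctly", {
  expo <- sumstats_df(paste0("v", 1:6),
                      ea = c("A", "A", "A", "C", "G", "A"),
                      oa = c("G", "G", "T", "G", "C", "C"),
                      eaf = c(0.3, 0.3, 0.50, 0.2, 0.3, 0.25),
                      beta = 1, se = 0.1, pval = 1e-5)
  outc <- sumstats_df(paste0("v", 1:6),
                      ea = c("A", "G", "A", "C", "C", "T"),
                      oa = c("G", "A", "T", "G", "G", "C"),
                      eaf = c(0.3, 0.7, 0.50, 0.2, 0.72, 0.4),
                      beta = c(0.5, 0.1, 0.2, 0.3, 0.4, 0.6),
                      se = 0.05, pval = 0.01)
  h <- harmonize(expo, outc)
  act <- setNames(h$harmonization_action, h$variant_id)
  # hand classification: v1 direct match; v2 swapped (flip); v3 palindromic
  # ambiguous; v4 palindromic (C/G) outside window, frequencies agree;
  # v5 palindromic, frequency mismatch -> flip; v6 irreconcilable
  expect_identical(unname(act[c("v1", "v2", "v3", "v4", "v5", "v6")]),
                   c("kept", "flipped", "dropped_palindromic", "kept",
                     "flipped", "dropped_mismatch"))
  expect_equal(h$beta_outcome[h$variant_id == "v2"], -0.1)
  expect_equal(h$eaf_outcome[h$variant_id == "v2"], 0.3)
  expect_error(harmonize(expo[-2], outc), "allele columns")
})

test_that("harmonization is idempotent on its own output", {
  expo <- sumstats_df(paste0("v", 1:3), c("A", "C", "A"), c("G", "T", "C"),
                      eaf = c(0.2, 0.4, 0.3), beta = c(1, 0.5, 2),
                      se = 0.1, pval = 1e-4)
  outc <- sumstats_df(paste0("v", 1:3), c("G", "C", "A"), c("A", "T", "C"),
                      eaf = c(0.8, 0.4, 0.3), beta = c(0.3, -0.2, 0.1),
                      se = 0.05, pval = 0.02)
  h1 <- harmonized_kept(harmonize(expo, outc))
  # rebuild both sides from the harmonized output and re-harmonize
  expo2 <- sumstats_df(h1$variant_id, h1$effect_allele, h1$other_allele,
                       h1$eaf_exposure, h1$beta_exposure, h1$se_exposure,
                       0.01)
  outc2 <- sumstats_df(h1$variant_id, h1$effect_allele, h1$other_allele,
                       h1$eaf_outcome, h1$beta_outcome, h1$se_outcome, 0.01)
  h2 <- harmonize(expo2, outc2)
  expect_true(all(h2$harmonization_action == "kept"))
  expect_equal(h2$beta_outcome, h1$beta_outcome)
  expect_equal(h2$beta_exposure, h1$beta_exposure)
})

test_that("GRS is the weighted dosage sum with mean imputation", {
  panel <- data.frame(variant_id = c("a", "b", "c"),
                      effect_allele = "A", other_allele = "G",
                      eaf = c(0.2, 0.5, 0.4),
                      weight_exposure = c(1.5, -0.5, 2))
  D <- rbind(c(0, 1, 2), c(2, 2, 0), c(1, NA, 1))
  colnames(D) <- panel$variant_id
  s <- compute_grs(D, panel)
  expect_equal(s[1], 0 * 1.5 + 1 * -0.5 + 2 * 2)
  expect_equal(s[2], 2 * 1.5 + 2 * -0.5 + 0)
  expect_equal(s[3], 1 * 1.5 + (2 * 0.5) * -0.5 + 1 * 2) # NA -> 2*eaf
  # zero weights -> zero scores; single unit weight -> identity
  panel0 <- panel; panel0$weight_exposure <- 0
  expect_true(all(compute_grs(D, panel0) == 0))
  p1 <- panel[1, ]; p1$weight_exposure <- 1
  expect_equal(compute_grs(D[, 1, drop = FALSE], p1), D[, 1])
  expect_error(compute_grs(D[, 1:2], panel), "columns")
})

test_that("instrument diagnostics match the closed-form OLS fit", {
  set.seed(31)
  g <- rnorm(10); v <- 2 + 0.8 * g + rnorm(10)
  d <- instrument_diagnostics(g, v)
  fit <- lm(v ~ g)
  expect_equal(d$diagnostics$r2, summary(fit)$r.squared, tolerance = 1e-12)
  expect_equal(d$residuals, unname(residuals(fit)) + mean(v),
               tolerance = 1e-12)
  # F identity and residual orthogonality
  r2 <- d$diagnostics$r2
  expect_equal(d$diagnostics$f_stat, r2 * 8 / (1 - r2), tolerance = 1e-12)
  expect_lt(abs(cor(d$residuals, g)), 1e-10)
  expect_error(instrument_diagnostics(rep(1, 10), v), "zero variance")
})

test_that("uncorrelated instruments give near-zero r2 and intact residuals", {
  set.seed(8)
  g <- rnorm(5000); v <- rnorm(5000, 50, 20)
  d <- instrument_diagnostics(g, v)
  expect_lt(d$diagnostics$r2, 0.002)
  expect_gt(cor(d$residuals, v), 0.999)
})

test_that("leave-block-out removes blocks and guards against emptiness", {
  fx <- default_cohort(n = 20000L, seed = 42L)
  panel <- fx$panel
  expect_equal(leave_block_out(panel, "none"), panel)
  expect_equal(leave_block_out(panel, "no_such_block"), panel)
  # single-variant (leave-one-out) exclusion
  lo <- leave_block_out(panel, panel$variant_id[2])
  expect_equal(nrow(lo), nrow(panel) - 1)
  # removing the dominant-weight transport block reduces variance explained
  reduced <- leave_block_out(panel, "vitamin D transport")
  D <- dosage_matrix(fx$cohort)
  full <- instrument_diagnostics(compute_grs(D, panel), fx$cohort$vitd)
  red <- instrument_diagnostics(compute_grs(D[, reduced$variant_id], reduced),
                                fx$cohort$vitd)
  expect_lt(red$diagnostics$r2, full$diagnostics$r2)
  all_blocks <- unique(panel$block)
  p2 <- panel
  for (b in all_blocks[-1]) p2 <- leave_block_out(p2, b)
  expect_error(leave_block_out(p2, all_blocks[1]), "zero instruments")
})
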
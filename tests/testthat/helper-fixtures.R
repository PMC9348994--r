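# shared fixtures, built in code

# toy harmonized-stats table with a known generating causal effect theta;
# optionally displace one variant's outcome beta by `displace_se` SEs
make_toy_harmonized <- function(seed, J = 35, theta = 0.05,
                                displace_se = 0, displace_idx = 7L) {
  set.seed(seed)
  bx <- runif(J, 0.3, 1.2)
  sx <- runif(J, 0.02, 0.05)
  sy <- runif(J, 0.02, 0.06)
  by <- rnorm(J, theta * bx, sy)
  if (displace_se != 0)
    by[displace_idx] <- theta * bx[displace_idx] +
      displace_se * sy[displace_idx]
  h <- data.frame(
    variant_id = paste0("v", seq_len(J)),
    effect_allele = "A", other_allele = "G",
    beta_exposure = bx, se_exposure = sx, eaf_exposure = 0.3,
    beta_outcome = by, se_outcome = sy, eaf_outcome = 0.3,
    harmonization_action = "kept", stringsAsFactors = FALSE)
  class(h) <- c("harmonized_stats", "data.frame")
  h
}

# hand-built harmonized table from explicit vectors
h_from_vectors <- function(bx, by, sx = rep(0.01, length(bx)),
                           sy = rep(0.1, length(bx))) {
  h <- data.frame(
    variant_id = paste0("v", seq_along(bx)),
    effect_allele = "A", other_allele = "G",
    beta_exposure = bx, se_exposure = sx, eaf_exposure = 0.3,
    beta_outcome = by, se_outcome = sy, eaf_outcome = 0.3,
    harmonization_action = "kept", stringsAsFactors = FALSE)
  class(h) <- c("harmonized_stats", "data.frame")
  h
}

# synthetic stratum_lace table with known derivative function and SEs
make_laces <- function(seed, x = seq(15, 95, length.out = 20),
                       dfun = function(x) rep(0.02, length(x)),
                       se = rep(0.005, length(x))) {
  set.seed(seed)
  y <- dfun(x) + rnorm(length(x), 0, se)
  d <- data.frame(index = seq_along(x), n = 1000L, n_events = 50L,
                  mean_exposure = x, beta_gx = 1, se_gx = 0.01,
                  beta_gy = y, se_gy = se, lace = y, se_lace = se,
                  outlier_flag = FALSE)
  class(d) <- c("stratum_lace", "data.frame")
  d
}

# moderate default cohort, built once per test run and memoised
.fixture_env <- new.env(parent = emptyenv())

default_cohort <- function(n = 20000L, seed = 42L, ...) {
  key <- paste0("cohort_", n, "_", seed, "_",
                paste(unlist(list(...)), collapse = "_"))
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  p <- sim_params(n_individuals = n, seed = seed, ...)
  panel <- simulate_panel(p)
  cohort <- simulate_cohort(panel, p)
  out <- list(params = p, panel = panel, cohort = cohort)
  .fixture_env[[key]] <- out
  out
}
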
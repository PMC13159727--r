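toy_obs <- function() {
  # observed counts over a 1D spectrum with 4 haploids
  sfs(c(0, 30, 12, 6, 0), "A", folded = FALSE)
}

toy_probs <- function(p) {
  s <- sfs(c(0, p, 0), "A", folded = FALSE)
  attr(s, "p_min") <- 1e-10
  s
}

test_that("composite log-likelihood matches direct arithmetic", {
  obs <- sfs(c(0, 3, 1, 0), "A")
  probs <- toy_probs(c(0.75, 0.25))
  expect_equal(composite_log_likelihood(obs, probs),
               3 * log(0.75) + 1 * log(0.25))
  # all observed mass on one cell with probability one
  obs1 <- sfs(c(0, 7, 0, 0), "A")
  expect_equal(composite_log_likelihood(obs1, toy_probs(c(1, 0)), p_min = 1e-300), 0)
  expect_error(composite_log_likelihood(obs, sfs(c(0, 1, 0, 0, 0), "A")),
               "different dimensions")
})

test_that("no probability vector beats the empirical proportions", {
  # Gibbs inequality, exercised with random observations and rivals
  set.seed(41)
  for (i in 1:25) {
    m <- rpois(3, 8) + 1
    obs <- sfs(c(0, m, 0), "A")
    mle <- toy_probs(m / sum(m))
    best <- composite_log_likelihood(obs, mle)
    rival <- runif(3); rival <- rival / sum(rival)
    expect_lte(composite_log_likelihood(obs, toy_probs(rival)), best + 1e-12)
  }
})

test_that("AIC follows both log conventions", {
  expect_equal(aic_from_log10(5, -1000), 2 * 5 - 2 * log(10) * (-1000))
  f <- structure(list(lnCL = -100, k = 4, AIC = 2 * 4 - 2 * (-100)),
                 class = "fit_result")
  expect_equal(f$AIC, 208)
})

test_that("ECM fitting recovers a single free parameter and is deterministic", {
  truth <- c(N_1 = 500, N_2 = 300, N_ANC = 500, T_1 = 2000, m = 1e-4)
  d <- build_named_model("within_C", truth, n_samples = 8)
  obs <- simulate_snp_sfs(d, 4000, n_genealogies = 1500, seed = 3)
  fixed <- truth[setdiff(names(truth), "T_1")]
  f1 <- fit_model_ecm("within_C", obs, n_sims = 1500, cycles = 2, seed = 9,
                      fixed = fixed)
  expect_equal(unname(f1$params["T_1"]), unname(truth["T_1"]), tolerance = 0.5)
  expect_equal(f1$AIC, 2 * 1 - 2 * f1$lnCL)
  expect_equal(length(f1$trace), 2)
  # bit-for-bit determinism under the same seed
  f2 <- fit_model_ecm("within_C", obs, n_sims = 1500, cycles = 2, seed = 9,
                      fixed = fixed)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$lnCL, f2$lnCL)
})

test_that("the lnCL trace is non-decreasing under common random numbers", {
  truth <- c(N_1 = 500, N_2 = 300, N_ANC = 500, T_1 = 2000, m = 1e-4)
  d <- build_named_model("within_C", truth, n_samples = 8)
  obs <- simulate_snp_sfs(d, 2000, n_genealogies = 1000, seed = 4)
  f <- fit_model_ecm("within_C", obs, n_sims = 800, cycles = 3, seed = 2,
                     fixed = truth[c("N_ANC", "m")], crn_across_cycles = TRUE)
  expect_true(all(diff(f$trace) >= -1e-9))
})

test_that("best-of-restarts can only improve the likelihood", {
  truth <- c(N_1 = 500, N_2 = 300, N_ANC = 500, T_1 = 2000, m = 1e-4)
  d <- build_named_model("within_C", truth, n_samples = 6)
  obs <- simulate_snp_sfs(d, 1500, n_genealogies = 800, seed = 5)
  fixed <- truth[setdiff(names(truth), c("T_1", "N_1"))]
  single <- fit_model_ecm("within_C", obs, n_sims = 600, cycles = 1, seed = 31,
                          fixed = fixed, n_restarts = 1)
  multi <- fit_model_ecm("within_C", obs, n_sims = 600, cycles = 1, seed = 31,
                         fixed = fixed, n_restarts = 3)
  expect_gte(multi$lnCL, single$lnCL)
})

test_that("model ranking sorts by AIC and validates its inputs", {
  mk <- function(model, lnCL, k, fp) structure(
    list(model = model, lnCL = lnCL, k = k, AIC = 2 * k - 2 * lnCL,
         obs_fingerprint = fp), class = "fit_result")
  fp <- c(dims = "5x5", total = 100, wsum = 1)
  f1 <- mk("m1", -500, 5, fp); f2 <- mk("m2", -500, 7, fp)
  rk <- compare_models(list(f1, f2))
  expect_equal(rk$model, c("m1", "m2"))      # equal lnCL: smaller k wins
  expect_equal(rk$delta_AIC, c(0, 4))
  # best-of-restarts per model
  f1b <- mk("m1", -490, 5, fp)
  rk2 <- compare_models(list(f1, f1b, f2))
  expect_equal(rk2$lnCL[rk2$model == "m1"], -490)
  expect_error(compare_models(list(f1)), "at least two")
  fp2 <- c(dims = "5x5", total = 90, wsum = 1)
  expect_error(compare_models(list(f1, mk("m3", -1, 1, fp2))), "different observed")
})

test_that("profile likelihood finds the simulated truth on a grid", {
  truth <- c(N_1 = 500, N_2 = 300, N_ANC = 500, T_1 = 2000, m = 1e-4)
  d <- build_named_model("within_C", truth, n_samples = 8)
  obs <- simulate_snp_sfs(d, 6000, n_genealogies = 2000, seed = 6)
  grid <- truth[["T_1"]] * seq(0.4, 1.8, by = 0.2)
  pr <- profile_likelihood("within_C", obs, "T_1", grid, fixed = truth,
                           n_sims = 3000, seed = 14)
  step <- which.min(abs(pr$profile$value - truth[["T_1"]]))
  expect_lte(abs(which.max(pr$profile$lnCL) - step), 1)
  expect_error(profile_likelihood("within_C", obs, "T_1", numeric(0),
                                  fixed = truth), "empty grid")
  expect_error(profile_likelihood("within_C", obs, "T_1", c(1, 10),
                                  fixed = truth), "outside parameter bounds")
})

test_that("bootstrap plumbing yields well-formed intervals", {
  truth <- c(N_1 = 500, N_2 = 300, N_ANC = 500, T_1 = 2000, m = 1e-4)
  d <- build_named_model("within_C", truth, n_samples = 6)
  obs <- simulate_snp_sfs(d, 1200, n_genealogies = 600, seed = 8)
  fixed <- truth[setdiff(names(truth), "T_1")]
  fit <- fit_model_ecm("within_C", obs, n_sims = 500, cycles = 1, seed = 3,
                       fixed = fixed)
  ci <- parametric_bootstrap_ci(fit, n_boot = 2, seed = 4, n_snps = 800,
                                n_sims = 400, cycles = 1)
  expect_s3_class(ci, "bootstrap_ci")
  expect_true(is.finite(ci$lower["T_1"]) && is.finite(ci$upper["T_1"]))
  expect_lte(ci$lower["T_1"], ci$upper["T_1"])
  expect_equal(ci$n_boot, 2)
})
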
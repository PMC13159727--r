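test_that("named models compile to valid event programs", {
  for (nm in c("origin_SW", "origin_C", "model1_stepping", "model2_SE_admix",
               "model3_NC_admix", "model4_SE_NC_admix", "model5_IM",
               "model6_independent", "within_SW", "within_C", "within_NC",
               "within_N")) {
    d <- build_named_model(nm)
    expect_s3_class(d, "demography")
    expect_true(all(d$demes$Ne > 0))
    # single-ancestor invariant is checked inside the constructor; reaching
    # here means lineage tracing succeeded
  }
})

test_that("model4 carries the reported admixture pulses in the right order", {
  d <- build_named_model("model4_SE_NC_admix",
                         c(default_params("model4_SE_NC_admix"),
                           T_SWC = 12850, T_CN = 10630, T_NC = 1350,
                           T_SE = 820)[names(default_params("model4_SE_NC_admix"))])
  ev <- d$events
  pulses <- ev[ev$kind == "admixture_pulse", ]
  expect_equal(nrow(pulses), 2)
  expect_equal(pulses$value[pulses$source == "SE"], 0.37)
  expect_equal(pulses$value[pulses$source == "NC"], 0.81)
  expect_equal(pulses$dest[pulses$source == "SE"], "SW")
  expect_equal(pulses$dest[pulses$source == "NC"], "N")
  # backward-time ordering: SE admixture < NC admixture < C/N split < SW/C split
  t_se <- pulses$time[pulses$source == "SE"]
  t_nc <- pulses$time[pulses$source == "NC"]
  t_cn <- ev$time[ev$kind == "split" & ev$source == "N"]
  t_swc <- ev$time[ev$kind == "split" & ev$source == "C"]
  expect_true(t_se < t_nc && t_nc < t_cn && t_cn < t_swc)
})

test_that("invalid model requests are rejected with named constraints", {
  expect_error(build_named_model("model99"), "unknown model")
  p <- default_params("model4_SE_NC_admix")
  expect_error(build_named_model("model4_SE_NC_admix", p[-1]), "missing parameter")
  p_bad <- p; p_bad["T_SE"] <- 2000  # > T_NC: violates event ordering
  expect_error(build_named_model("model4_SE_NC_admix", p_bad),
               "event-time ordering")
  p_oob <- p; p_oob["N_SW"] <- 5  # below the prior lower bound
  expect_error(build_named_model("model4_SE_NC_admix", p_oob), "outside bounds")
})

test_that("a demography with no route to a common ancestor is rejected", {
  expect_error(
    demography(data.frame(label = c("A", "B"), Ne = 100, n_samples = 2)),
    "one ancestral deme")
  # with validation off, the simulator raises the diagnostic instead
  d <- demography(data.frame(label = c("A", "B"), Ne = 100, n_samples = 2),
                  check_ancestry = FALSE)
  expect_error(simulate_sfs(d, 5, seed = 1), "never coalesces")
})

test_that("an admixture pulse of fraction 1 is exactly a split", {
  d_split <- build_named_model("model1_stepping",
                               default_params("model1_stepping"), n_samples = 4)
  p4 <- default_params("model4_SE_NC_admix")
  p4["a_SE"] <- 1; p4["a_NC"] <- 1
  d_pulse <- build_named_model("model4_SE_NC_admix", p4, n_samples = 4)
  # identical seed streams must give bit-identical branch-length spectra
  s1 <- expected_sfs_probs(d_split, 300, seed = 99)
  s2 <- expected_sfs_probs(d_pulse, 300, seed = 99)
  expect_identical(s1$counts, s2$counts)
})

test_that("shared polymorphism vanishes as the split deepens without migration", {
  shared <- vapply(c(200, 2000, 20000), function(Tsplit) {
    s <- simulate_sfs(two_deme_split(Tsplit, Ne = 500, n = 4, mu = 5e-4),
                      3000, seed = 7)
    a <- s$counts
    both <- sum(a[2:4, 2:4])       # segregating in both demes
    both / max(1, sum(a * polymorphic_mask(s)))
  }, numeric(1))
  expect_true(all(diff(shared) < 0))
  expect_lt(shared[3], 0.02)
})

test_that("time unit conversion respects the 10-year generation time", {
  expect_equal(ka_to_gen(128.5), 12850)
  expect_equal(gen_to_ka(10630), 106.3)
  expect_equal(ka_to_gen(gen_to_ka(820)), 820)
})

test_that("model definition files round-trip losslessly", {
  spec <- list(model = "model4_SE_NC_admix",
               fixed = list(N_SW = 5000, m = 1e-4),
               free = list(T_SWC = c(100, 50000), a_SE = c(0.001, 0.999)))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_spec(spec, path)
  back <- read_model_spec(path)
  expect_equal(back$model, spec$model)
  expect_equal(back$fixed, lapply(spec$fixed, as.numeric))
  expect_equal(back$free, lapply(spec$free, as.numeric))
})
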
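test_that("observed heterozygosity matches direct counting", {
  geno <- rbind(allhet = rep(1L, 10), allhom = rep(c(0L, 2L), 5),
                mix = c(1L, 1L, 0L, 2L, NA, NA, 1L, 0L, 0L, 0L))
  ho <- observed_heterozygosity(geno)
  expect_equal(unname(ho["allhet"]), 1)
  expect_equal(unname(ho["allhom"]), 0)
  expect_equal(unname(ho["mix"]), 3 / 8)
  expect_error(observed_heterozygosity(rbind(x = rep(NA_integer_, 4))),
               "all genotypes missing")
})

test_that("heterozygosity under HWE at p = 0.5 is near one half", {
  set.seed(6)
  n_sites <- 4000
  geno <- matrix(rbinom(5 * n_sites, 2L, 0.5), 5, n_sites,
                 dimnames = list(paste0("i", 1:5), NULL))
  ho <- observed_heterozygosity(geno)
  se <- sqrt(0.5 * 0.5 / n_sites)
  expect_true(all(abs(ho - 0.5) < 3 * se))
})

test_that("WC84 F_ST behaves at its anchor points", {
  set.seed(13)
  pm <- setNames(rep(c("P1", "P2"), each = 12), sprintf("i%02d", 1:24))
  # identical allele frequencies: F_ST ~ 0
  p <- runif(10000, 0.1, 0.9)
  g <- t(replicate(24, rbinom(10000, 2L, p)))
  rownames(g) <- names(pm)
  f0 <- pairwise_fst(g, pm)["P1", "P2"]
  expect_lt(abs(f0), 0.01)
  # reciprocally fixed differences: F_ST = 1
  gfix <- rbind(matrix(0L, 12, 50), matrix(2L, 12, 50))
  rownames(gfix) <- names(pm)
  expect_equal(pairwise_fst(gfix, pm)["P1", "P2"], 1)
  # invariance to allele-label swap and individual order
  g2 <- 2L - g[sample(nrow(g)), ]
  expect_equal(pairwise_fst(g2, pm)["P1", "P2"], f0, tolerance = 1e-12)
  expect_error(pairwise_fst(g[1:13, ], pm), "< 2 individuals")
})

test_that("vectorized F_ST equals the per-site variance components", {
  set.seed(21)
  pm <- setNames(rep(c("P1", "P2"), times = c(6, 9)), sprintf("i%02d", 1:15))
  g <- matrix(rbinom(15 * 200, 2L, rep(runif(200, 0.05, 0.95), each = 15)),
              15, 200, dimnames = list(names(pm), NULL))
  g[sample(length(g), 100)] <- NA
  comp <- vapply(seq_len(ncol(g)), function(s)
    rhinopop:::.wc_components(g[1:6, s], g[7:15, s]), numeric(2))
  want <- sum(comp[1, ]) / sum(comp[2, ])
  expect_equal(pairwise_fst(g, pm)["P1", "P2"], want, tolerance = 1e-12)
})

test_that("F_ST linearization is exact and monotone", {
  expect_equal(linearize_fst(0), 0)
  expect_equal(linearize_fst(0.5), 1)
  expect_equal(linearize_fst(0.2), 0.25)
  expect_equal(linearize_fst(-0.03), 0)          # negatives clamp to zero
  x <- seq(0, 0.99, by = 0.01)
  expect_true(all(diff(linearize_fst(x)) > 0))
  expect_error(linearize_fst(1), "infinite")
})

test_that("haversine distances match closed-form references", {
  co <- data.frame(label = c("a", "b"), lat = c(0, 1), lon = c(10, 10))
  d <- geographic_distances(co)
  expect_equal(d["a", "b"], 111.2, tolerance = 0.005)
  anti <- data.frame(label = c("x", "y"), lat = c(10, -10), lon = c(0, 180))
  expect_equal(geographic_distances(anti)["x", "y"], 20015, tolerance = 0.001)
  expect_equal(geographic_distances(co)["a", "a"], 0)
  expect_error(geographic_distances(data.frame(label = "z", lat = 95, lon = 0)),
               "out of range")
})

test_that("Mantel p-value matches exhaustive enumeration on 4 labels", {
  set.seed(15)
  for (rep in 1:5) {
    m1 <- as.matrix(dist(runif(4))); m2 <- as.matrix(dist(runif(4)))
    dimnames(m1) <- dimnames(m2) <- list(letters[1:4], letters[1:4])
    exact <- mantel_test_exact(m1, m2)
    # sampled p converges to the exhaustive p (both one-sided, >=)
    mt <- mantel_test(m1, m2, n_perm = 4999, seed = rep)
    expect_equal(mt$p, exact$p, tolerance = 0.05)
    expect_equal(mt$r, exact$r)
  }
})

test_that("identical matrices give the minimal one-sided p", {
  set.seed(77)
  m <- as.matrix(dist(runif(10)))
  dimnames(m) <- list(letters[1:10], letters[1:10])
  mt <- mantel_test(m, m, n_perm = 99, seed = 5)
  expect_equal(mt$r, 1)
  expect_equal(mt$p, 1 / 100)
  expect_error(mantel_test(m * 0, m, n_perm = 99), "constant")
})

test_that("our Mantel statistic agrees with vegan on the same matrices", {
  skip_if_not_installed("vegan")
  set.seed(23)
  m1 <- as.matrix(dist(runif(8))); m2 <- as.matrix(dist(runif(8)))
  dimnames(m1) <- dimnames(m2) <- list(letters[1:8], letters[1:8])
  ours <- mantel_test(m1, m2, n_perm = 999, seed = 3)
  ref <- vegan::mantel(m1, m2, permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p - ref$signif), 0.03)
})

test_that("a stepping-stone lattice produces detectable isolation by distance", {
  # 6-deme 1D lattice with nearest-neighbour migration; genetic distance
  # should correlate with lattice position
  k <- 6
  labs <- paste0("L", 1:k)
  mig <- matrix(0, k, k)
  for (i in seq_len(k - 1)) mig[i, i + 1] <- mig[i + 1, i] <- 5e-4
  d <- demography(
    data.frame(label = labs, Ne = 500, n_samples = 8),
    events = data.frame(time = 8000, kind = "split",
                        source = labs[2:k], dest = "L1", value = 0),
    migration0 = mig, mu = 1e-4)
  hits <- 0
  for (rep in 1:5) {
    ch <- simulate_genotype_matrix(
      d, data.frame(group = labs, cluster = labs, n = 6), n_sites = 400,
      group_fst = 0, freq_haploids = 16, seed = 100 + rep)
    f <- pairwise_fst(ch$geno, ch$pop_map, labs)
    gen_d <- linearize_fst(f)
    geo <- abs(outer(1:k, 1:k, "-")) * 50
    dimnames(geo) <- list(labs, labs)
    mt <- mantel_test(gen_d, geo, n_perm = 999, seed = rep)
    if (mt$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 4)
})
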
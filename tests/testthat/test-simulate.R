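test_that("single-deme mean SFS matches the Watterson expectation", {
  # E[xi_i] = theta / i per locus; MC standard error estimated over batches
  theta <- 4 * 2500 * 1e-4
  d <- single_deme(Ne = 2500, n = 4, mu = 1e-4)
  n_batches <- 20; loci_per_batch <- 600
  batch_means <- t(vapply(seq_len(n_batches), function(b) {
    s <- simulate_sfs(d, loci_per_batch, seed = 1000 + b)
    as.vector(s$counts)[2:4] / loci_per_batch
  }, numeric(3)))
  est <- colMeans(batch_means)
  se <- apply(batch_means, 2, stats::sd) / sqrt(n_batches)
  expect_true(all(abs(est - theta / (1:3)) < 3 * se + 1e-12))
})

test_that("mutation rate zero gives an all-zero spectrum", {
  d <- single_deme(mu = 0)
  s <- simulate_sfs(d, 50, seed = 3)
  expect_true(all(s$counts == 0))
  expect_equal(attr(s, "n_monomorphic_loci"), 50)
})

test_that("expected probabilities follow the harmonic law in a single deme", {
  d <- single_deme(n = 6)
  p <- expected_sfs_probs(d, 4000, seed = 5)
  got <- as.vector(p$counts)[2:6]
  want <- (1 / (1:5)) / sum(1 / (1:5))
  expect_true(all(abs(got - want) < 0.01))
  expect_equal(sum(p$counts), 1, tolerance = 1e-12)
})

test_that("Monte-Carlo error of expected probabilities shrinks like 1/sqrt(n)", {
  d <- single_deme(n = 6)
  dev <- vapply(c(400, 6400), function(ns) {
    p1 <- expected_sfs_probs(d, ns, seed = 11)
    p2 <- expected_sfs_probs(d, ns, seed = 12)
    max(abs(p1$counts - p2$counts))
  }, numeric(1))
  # 16x the simulations should shrink the seed-to-seed gap ~4x; allow slack
  expect_lt(dev[2], dev[1] / 1.5)
})

test_that("a symmetric two-deme model gives an exchangeable 2D spectrum", {
  d <- demography(
    data.frame(label = c("P1", "P2"), Ne = 1000, n_samples = 4),
    events = data.frame(time = 2000, kind = "split", source = "P2",
                        dest = "P1", value = 0),
    migration0 = matrix(c(0, 1e-3, 1e-3, 0), 2, 2), mu = 1e-4)
  p <- expected_sfs_probs(d, 20000, seed = 8)
  asym <- max(abs(p$counts - t(p$counts)))
  expect_lt(asym, 0.01)
})

test_that("conditional-site sampling agrees with branch-length probabilities", {
  d <- two_deme_split(1500, Ne = 800, n = 4, m = 1e-3)
  p <- expected_sfs_probs(d, 20000, seed = 21)
  s <- simulate_snp_sfs(d, 40000, n_genealogies = 8000, seed = 22)
  emp <- s$counts / sum(s$counts)
  expect_lt(max(abs(emp - p$counts)), 0.012)
})

test_that("identical seeds reproduce simulations exactly", {
  d <- build_named_model("model4_SE_NC_admix", n_samples = 4)
  expect_identical(simulate_sfs(d, 200, seed = 42)$counts,
                   simulate_sfs(d, 200, seed = 42)$counts)
  expect_identical(simulate_snp_sfs(d, 500, 200, seed = 42)$counts,
                   simulate_snp_sfs(d, 500, 200, seed = 42)$counts)
})

test_that("the genotype generator honours its contract", {
  d <- build_named_model("model4_SE_NC_admix")
  groups <- data.frame(group = c("g1", "g2", "g3", "g4", "g5"),
                       cluster = c("SW", "SE", "C", "NC", "N"), n = 6)
  ch <- simulate_genotype_matrix(d, groups, n_sites = 800, missing_rate = 0,
                                 relative_pairs = 1, seed = 5)
  expect_false(anyNA(ch$geno))          # missing_rate 0 -> nothing missing
  expect_equal(nrow(ch$geno), 30)
  expect_equal(nrow(ch$relatives), 1)
  expect_true(all(c(ch$relatives$parent, ch$relatives$child) %in% rownames(ch$geno)))
  # Mendelian consistency: an AA parent cannot have an aa child and vice versa
  pa <- ch$geno[ch$relatives$parent[1], ]
  kid <- ch$geno[ch$relatives$child[1], ]
  expect_true(all(!(pa == 2 & kid == 0)))
  expect_true(all(!(pa == 0 & kid == 2)))
  bad_groups <- groups; bad_groups$cluster[1] <- "XX"
  expect_error(simulate_genotype_matrix(d, bad_groups, n_sites = 10),
               "absent from demography")
})

test_that("deep isolation between demes drives F_ST towards one", {
  d <- two_deme_split(3e4, Ne = 300, n = 20, m = 0, mu = 1e-4)
  groups <- data.frame(group = c("a", "b"), cluster = c("P1", "P2"), n = 8)
  ch <- simulate_genotype_matrix(d, groups, n_sites = 600, missing_rate = 0,
                                 group_fst = 0, freq_haploids = 20, seed = 9)
  f <- pairwise_fst(ch$geno, ch$pop_map)
  expect_gt(f["P1", "P2"], 0.8)
})
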
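make_records <- function() {
  # 10 hand-written records; failures annotated per row
  data.frame(
    id = sprintf("s%02d", 1:10),
    biallelic = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    QUAL = c(100, 59.9, 100, 100, 100, 100, 100, 60, 100, 100),
    FS   = c(5, 5, 60.1, 5, 5, 5, 5, 60, 5, 5),
    QD   = c(20, 20, 20, 1.5, 20, 20, 20, 2, 20, 20),
    MQ   = c(55, 55, 55, 55, 39.5, 55, 55, 40, 55, 55),
    MQRankSum = c(0, 0, 0, 0, 0, -25, 0, -20, 0, NA),
    ReadPosRankSum = c(0, 0, 0, 0, 0, 0, -9, -8, 0, 0),
    maf = c(0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.05, 0.3, 0.01),
    missingness = c(0, 0, 0, 0, 0, 0, 0, 0.2, 0, 0))
  # expected removals: s02 QUAL, s03 FS, s04 QD, s05 MQ, s06 MQRankSum,
  # s07 ReadPosRankSum, s09 nonbiallelic, s10 MAF (RankSum NA skipped);
  # s01 passes; s08 sits exactly on every boundary and passes
}

test_that("site hard filters match the hand-derived outcome", {
  res <- filter_sites(make_records())
  expect_equal(res$sites$id, c("s01", "s08"))
  rb <- res$report$removed_by_rule
  expect_equal(rb$QUAL, 1); expect_equal(rb$FS, 1); expect_equal(rb$QD, 1)
  expect_equal(rb$MQ, 1); expect_equal(rb$MQRankSum, 1)
  expect_equal(rb$ReadPosRankSum, 1); expect_equal(rb$nonbiallelic, 1)
  expect_equal(rb$MAF, 1)
  # report conservation: attributed removals sum to input - output
  expect_equal(sum(unlist(rb)), res$report$n_input - res$report$n_kept)
  # missing annotation is skipped, not failed
  expect_equal(res$report$skipped_missing_annotation$MQRankSum, 1)
})

test_that("filtering is idempotent and boundary values pass", {
  res1 <- filter_sites(make_records())
  res2 <- filter_sites(res1$sites)
  expect_equal(res2$sites$id, res1$sites$id)
  expect_equal(res2$report$n_input, res2$report$n_kept)
  # s08: QUAL = 60, FS = 60, QD = 2, MQ = 40, ranksums at bounds, MAF = 0.05
  expect_true("s08" %in% res1$sites$id)
})

test_that("individual filters apply the depth/missingness rules", {
  ind <- data.frame(id = c("a", "b", "c", "d"),
                    mean_depth = c(10, 3.9, 4.0, 30),
                    missing_rate = c(0.29, 0.1, 0.31, 0.305))
  res <- filter_individuals(ind)
  expect_equal(res$kept, "a")          # b: depth; c and d: missingness
  expect_equal(sort(res$removed), c("b", "c", "d"))
  expect_equal(res$report$n_input - res$report$n_kept,
               sum(unlist(res$report$removed_by_rule)))
})

test_that("QC recovers the planted low-quality individuals exactly", {
  d <- build_named_model("model4_SE_NC_admix")
  groups <- default_group_design(60)
  ch <- simulate_genotype_matrix(d, groups, n_sites = 400, low_quality = 10,
                                 seed = 17)
  res <- filter_individuals(ch$individuals)
  expect_setequal(res$removed, ch$individuals$id[ch$individuals$true_low_quality])
})

test_that("the HWE exact test equals brute-force enumeration", {
  expect_equal(hwe_exact_test(100, 0, 0), 1)           # monomorphic
  expect_lt(hwe_exact_test(50, 0, 50), 1e-10)          # extreme het deficit
  # exhaustive over all configurations with up to 25 genotypes
  for (n in c(2, 5, 11, 25)) {
    for (nAA in 0:n) for (nAa in 0:(n - nAA)) {
      naa <- n - nAA - nAa
      expect_equal(hwe_exact_test(nAA, nAa, naa), hwe_oracle(nAA, nAa, naa),
                   tolerance = 1e-9)
    }
  }
  # randomized configurations up to n = 200
  set.seed(31)
  for (k in 1:300) {
    n <- sample(3:200, 1)
    cnt <- as.vector(stats::rmultinom(1, n, runif(3)))
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 hwe_oracle(cnt[1], cnt[2], cnt[3]), tolerance = 1e-9)
  }
})

test_that("KING kinship hits its theoretical anchors", {
  geno <- hwe_cohort(n_ind = 10, n_sites = 10000, seed = 7, po_pair = TRUE)
  geno <- rbind(geno, dup01 = geno["ind05", ])   # planted duplicate
  K <- king_kinship(geno)
  expect_identical(K, t(K))                      # bit-exact symmetry
  expect_equal(K["ind05", "dup01"], 0.5, tolerance = 0.02)
  expect_gt(K["ind01", "ind03"], 0.177)          # parent-offspring
  expect_lt(K["ind01", "ind03"], 0.35)
  # unrelated pairs scatter around zero (per-pair sd ~ 0.011 at 1e4 sites):
  # the average magnitude stays under 0.02 and no pair approaches 0.177
  unrel <- K[4:10, 4:10]; unrel[lower.tri(unrel, diag = TRUE)] <- NA
  expect_lt(mean(abs(unrel), na.rm = TRUE), 0.02)
  expect_lt(max(abs(unrel), na.rm = TRUE), 0.05)
  # zero-overlap pair is NA, not zero
  g2 <- rbind(x = c(0L, 1L, NA, NA), y = c(NA, NA, 1L, 2L))
  expect_true(is.na(king_kinship(g2)["x", "y"]))
})

test_that("first-degree pruning is a minimal greedy vertex cover", {
  ids <- c("A", "B", "C", "D", "E")
  K <- matrix(0, 5, 5, dimnames = list(ids, ids))
  K["A", "B"] <- K["B", "A"] <- 0.25      # chain A-B, B-C: remove B only
  K["B", "C"] <- K["C", "B"] <- 0.30
  K["D", "E"] <- K["E", "D"] <- 0.20      # disjoint pair: remove one
  diag(K) <- 0.5
  res <- prune_first_degree(K)
  expect_true("B" %in% res$removed)
  expect_equal(length(res$removed), 2)
  kept <- K[res$kept, res$kept]; diag(kept) <- 0
  expect_true(all(kept <= 0.177))
  # no pair above threshold: everything kept
  K0 <- matrix(0.1, 3, 3, dimnames = list(ids[1:3], ids[1:3])); diag(K0) <- 0.5
  expect_equal(prune_first_degree(K0)$removed, character(0))
  # k disjoint flagged pairs: exactly k removed
  ids6 <- letters[1:6]
  K6 <- matrix(0, 6, 6, dimnames = list(ids6, ids6)); diag(K6) <- 0.5
  for (i in c(1, 3, 5)) K6[i, i + 1] <- K6[i + 1, i] <- 0.3
  expect_equal(length(prune_first_degree(K6)$removed), 3)
})

test_that("panel design reproduces a hand-derived survivor list", {
  # 30 sites on two chromosomes; rules applied in documented order
  set.seed(44)
  n <- 30
  sites <- data.frame(
    chrom = rep(c("chr1", "chr2"), each = 15),
    pos = rep(c(seq(1000, 43000, by = 3000)), 2),
    id = sprintf("t%02d", 1:30),
    biallelic = TRUE, autosomal = TRUE)
  # genotypes: 40 individuals in HWE at maf 0.3, fully typed
  geno <- matrix(rbinom(40 * n, 2L, 0.3), 40, n)
  geno[1, 2] <- NA                                  # t02: incomplete
  geno[, 3] <- rbinom(40, 2L, 0.02)                 # t03: low MAF
  geno[, 4] <- c(rep(0L, 20), rep(2L, 20))          # t04: extreme HWE deficit
  sites$biallelic[5] <- FALSE                       # t05: not biallelic
  gene_mask <- data.frame(chrom = "chr1", start = 15500, end = 20000)  # hits t06 (pos 16000) & t07 (19000)
  cpg_mask <- data.frame(chrom = "chr2", start = 0, end = 1500)        # hits t16 (pos 1000)
  res <- design_panel(sites, geno, gene_mask, cpg_mask)
  # hand application: drop t02-t07, t16; then thin to one per 10 kb window
  surv <- res$panel$id
  expect_false(any(c("t02", "t03", "t04", "t05", "t06", "t07", "t16") %in% surv))
  # thinning: windows [0,10k) [10k,20k) ... keep first surviving site each
  pos_by_chrom <- split(res$panel$pos, res$panel$chrom)
  for (p in pos_by_chrom) expect_true(!anyDuplicated((p - 1) %/% 10000))
  expect_equal(res$report$n_input - res$report$n_kept,
               sum(unlist(res$report$removed_by_rule)))
  # two passing SNPs 5 kb apart: only one retained
  s2 <- data.frame(chrom = "chr1", pos = c(1000, 6000), id = c("x1", "x2"),
                   biallelic = TRUE, autosomal = TRUE)
  g2 <- matrix(rbinom(40 * 2, 2L, 0.4), 40, 2)
  expect_equal(design_panel(s2, g2)$panel$id, "x1")
})
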
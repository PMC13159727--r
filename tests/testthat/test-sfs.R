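test_that("joint_sfs matches a hand tally on a toy two-population matrix", {
  # 4 individuals (2 per pop), 6 sites, hand-derived cell placements
  geno <- rbind(a1 = c(0L, 1L, 2L, 0L, 1L, 0L),
                a2 = c(0L, 1L, 2L, 0L, 0L, 0L),
                b1 = c(1L, 0L, 2L, 0L, 2L, 0L),
                b2 = c(0L, 0L, 2L, 0L, 2L, NA))
  pm <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  s <- joint_sfs(geno, pm, c("A", "B"), folded = FALSE)
  expect_equal(attr(s, "n_dropped_missing"), 1)   # site 6 is complete-case dropped
  # derived counts (A, B): site1 (0,1); site2 (2,0); site3 (4,4) fixed;
  # site4 (0,0) monomorphic; site5 (1,4)
  want <- array(0, dim = c(5, 5))
  want[1, 2] <- 1; want[3, 1] <- 1; want[5, 5] <- 1; want[1, 1] <- 1
  want[2, 5] <- 1
  expect_equal(s$counts, want)
  # monomorphic corners are excluded from the polymorphic mask
  expect_equal(sum(polymorphic_mask(s) * s$counts), 3)
})

test_that("folding matches its definition on a 1D spectrum", {
  u <- sfs(c(0, 5, 3, 2, 1), "A", folded = FALSE)   # n = 4 haploids
  f <- fold_sfs(u)
  expect_equal(as.vector(f$counts), c(0 + 1, 5 + 2, 3, 0, 0))
  expect_equal(sum(f$counts), sum(u$counts))        # mass conserved
  expect_true(f$folded)
})

test_that("projection satisfies the hypergeometric closed form", {
  # singleton at n = 4 projected to n' = 2: C(1,1)C(3,1)/C(4,2) = 1/2
  u <- sfs(c(0, 1, 0, 0, 0), "A")
  pr <- project_sfs(u, 2)
  expect_equal(as.vector(pr$counts), c(0.5, 0.5, 0))
  # identity projection
  expect_equal(project_sfs(u, 4)$counts, u$counts)
  expect_error(project_sfs(u, 6), "exceeds source")
})

test_that("projection conserves mass and is linear", {
  set.seed(4)
  a1 <- array(rpois(5 * 7, 3), dim = c(5, 7))
  a2 <- array(rpois(5 * 7, 2), dim = c(5, 7))
  s1 <- sfs(a1, c("A", "B")); s2 <- sfs(a2, c("A", "B"))
  p1 <- project_sfs(s1, c(2, 4)); p2 <- project_sfs(s2, c(2, 4))
  expect_equal(sum(p1$counts), sum(a1), tolerance = 1e-9)
  comb <- sfs(2 * a1 + 3 * a2, c("A", "B"))
  expect_equal(project_sfs(comb, c(2, 4))$counts,
               2 * p1$counts + 3 * p2$counts, tolerance = 1e-9)
})

test_that("marginalization sums dropped axes and is consistent", {
  set.seed(9)
  a <- array(rpois(4 * 5 * 3, 2), dim = c(4, 5, 3))
  s <- sfs(a, c("A", "B", "C"))
  mAB <- marginalize_sfs(s, c("A", "B"))
  expect_equal(dim(mAB$counts), c(4, 5))
  expect_equal(sum(mAB$counts), sum(a))
  expect_equal(as.vector(marginalize_sfs(mAB, "A")$counts),
               as.vector(marginalize_sfs(s, "A")$counts))
  expect_equal(sum(marginalize_sfs(s, "C")$counts), sum(a))
  expect_error(marginalize_sfs(s, character(0)), "empty")
  expect_error(marginalize_sfs(s, "Z"), "unknown")
})

test_that("marginalizing the joint SFS equals the single-population SFS", {
  set.seed(12)
  geno <- matrix(rbinom(6 * 50, 2L, 0.3), 6, 50,
                 dimnames = list(sprintf("i%d", 1:6), NULL))
  pm <- setNames(rep(c("A", "B"), each = 3), rownames(geno))
  joint <- joint_sfs(geno, pm, c("A", "B"), folded = FALSE)
  solo <- joint_sfs(geno[1:3, , drop = FALSE], pm, "A", folded = FALSE)
  expect_equal(as.vector(marginalize_sfs(joint, "A")$counts),
               as.vector(solo$counts))
})

test_that("SFS files round-trip in both dialects", {
  set.seed(2)
  s <- sfs(array(rpois(5 * 5, 2), dim = c(5, 5)), c("SW", "C"), folded = TRUE)
  pj <- withr::local_tempfile(fileext = ".json")
  pf <- withr::local_tempfile(fileext = ".obs")
  write_sfs(s, pj, "json")
  back <- read_sfs(pj, "json")
  expect_equal(back$counts, s$counts)
  expect_equal(back$pops, s$pops)
  expect_true(back$folded)
  write_sfs(s, pf, "fsc")
  expect_equal(readLines(pf)[1], "1 observations")
  back2 <- read_sfs(pf, "fsc")
  expect_equal(back2$counts, s$counts)
  expect_equal(back2$pops, s$pops)
})
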
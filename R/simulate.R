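.seed_int <- function(seed) {
  s <- as.numeric(seed)
  if (!is.finite(s) || s < 0) stop("seed must be a non-negative integer")
  s
}

.sampled_pops <- function(demog) demog$demes$label[demog$demes$n_samples > 0]

#' Simulate a joint SFS by coalescent simulation with infinite-sites mutation
#'
#' Simulates \code{n_loci} independent non-recombining loci under the
#' structured coalescent defined by \code{demog}; the number of mutations per
#' locus is Poisson with mean \code{mu} times the total genealogy branch
#' length, and each mutation is placed on a branch with probability
#' proportional to its length (fastsimcoal DNA/SNP convention). Loci with no
#' mutation are counted as monomorphic. Reproducible given \code{seed}
#' (per-locus streams are derived by a counter-based splitter, so results do
#' not depend on execution order).
#'
#' @param demog a \code{\link{demography}} with at least one sampled deme.
#' @param n_loci number of independent loci.
#' @param seed integer root seed.
#' @param folded fold the resulting spectrum (default FALSE: simulated data
#'   are polarized by construction).
#' @return an \code{sfs} of mutation counts; attributes
#'   \code{n_monomorphic_loci} and \code{n_mutations}.
#' @export
simulate_sfs <- function(demog, n_loci, seed, folded = FALSE) {
  stopifnot(inherits(demog, "demography"), n_loci >= 1)
  if (sum(demog$demes$n_samples) < 2) stop("need at least 2 sampled lineages")
  res <- cpp_mutation_sfs(.demog_cpp(demog), as.integer(n_loci), demog$mu,
                          .seed_int(seed))
  out <- sfs(array(res$cells, dim = res$dims), .sampled_pops(demog))
  if (folded) out <- fold_sfs(out)
  attr(out, "n_monomorphic_loci") <- res$n_monomorphic_loci
  attr(out, "n_mutations") <- res$n_mutations
  out
}

#' Expected SFS cell probabilities by branch-length Monte Carlo
#'
#' Estimates the probability that a segregating site falls in each joint-SFS
#' cell: over \code{n_sims} simulated genealogies, every branch contributes
#' its length to the cell of its descendant configuration, and the
#' accumulated lengths are normalized over polymorphic cells. This is the
#' low-variance estimator used by simulation-based composite-likelihood
#' fitting. Cells never reached by simulation keep probability zero here;
#' the composite likelihood substitutes \code{p_min} (default
#' \code{1/(10 n_sims)}, recorded as an attribute) for observed cells with
#' zero simulated mass. Flooring the full vector would add spurious mass
#' proportional to the number of empty cells and bias comparisons across
#' parameter values, so the floor is deliberately confined to the
#' likelihood.
#'
#' @param demog a \code{\link{demography}}.
#' @param n_sims number of simulated genealogies (>= 100).
#' @param seed integer root seed.
#' @param p_min probability floor recorded for downstream likelihoods.
#' @param folded fold the expected spectrum before normalizing.
#' @return an \code{sfs} whose polymorphic cells hold probabilities summing
#'   to 1 (monomorphic corners are 0); attribute \code{mean_total_length}.
#' @export
expected_sfs_probs <- function(demog, n_sims, seed,
                               p_min = 1 / (10 * n_sims), folded = FALSE) {
  stopifnot(inherits(demog, "demography"), n_sims >= 100, p_min > 0)
  res <- cpp_branch_sfs(.demog_cpp(demog), as.integer(n_sims),
                        .seed_int(seed))
  out <- sfs(array(res$cells, dim = res$dims), .sampled_pops(demog))
  if (folded) out <- fold_sfs(out)
  mask <- polymorphic_mask(out)
  p <- out$counts
  p[!mask] <- 0
  tot <- sum(p)
  if (tot <= 0) stop("no polymorphic branch mass simulated")
  out$counts <- p / tot
  attr(out, "mean_total_length") <- res$mean_total_length
  attr(out, "p_min") <- p_min
  out
}

#' Simulate the joint SFS of a fixed number of segregating SNPs
#'
#' Draws \code{n_snps} sites conditional on polymorphism: genealogies are
#' sampled with probability proportional to total branch length and the
#' mutated branch proportional to its length within the genealogy — the
#' infinite-sites distribution of a segregating site, and exactly the
#' multinomial model assumed by the SFS composite likelihood. Used to emulate
#' SNP-panel data, where the number of segregating sites is fixed by design.
#'
#' @param demog a \code{\link{demography}}.
#' @param n_snps number of segregating sites to draw.
#' @param n_genealogies number of distinct genealogies to simulate (sites
#'   drawn from the same genealogy are linked; keep this comfortably above
#'   \code{n_snps / 10}).
#' @param seed integer root seed.
#' @param folded fold the spectrum.
#' @return an \code{sfs} of integer site counts summing to \code{n_snps}.
#' @export
simulate_snp_sfs <- function(demog, n_snps, n_genealogies = 2000, seed,
                             folded = FALSE) {
  stopifnot(inherits(demog, "demography"), n_snps >= 1, n_genealogies >= 10)
  cnt <- cpp_conditional_sites(.demog_cpp(demog), as.integer(n_snps),
                               as.integer(n_genealogies), .seed_int(seed))
  pops <- .sampled_pops(demog)
  n_hap <- demog$demes$n_samples[demog$demes$n_samples > 0]
  dims <- n_hap + 1L
  idx <- as.integer(cnt %*% cumprod(c(1, dims[-length(dims)]))) + 1L
  counts <- array(tabulate(idx, nbins = prod(dims)), dim = dims)
  out <- sfs(counts, pops)
  if (folded) out <- fold_sfs(out)
  out
}

#' Simulate a genotype cohort emulating the targeted-capture study design
#'
#' Generates a diploid genotype matrix for sampling groups nested in the
#' genetic clusters of \code{demog}: per-site cluster allele frequencies come
#' from coalescent-simulated segregating sites (frequency resolution
#' \code{freq_haploids} haploids per cluster), each group's frequency is drawn
#' around its cluster frequency with a Balding-Nichols beta deviate of
#' divergence \code{group_fst}, and genotypes are Hardy-Weinberg draws within
#' groups. The generator plants ground truth for the QC stages: first-degree
#' relatives, low-quality individuals (low mean depth and elevated missingness), and
#' per-site QUAL/FS/QD/MQ/MQRankSum/ReadPosRankSum annotations drawn from
#' pass/fail mixtures with known fail labels. Each planted child is generated
#' by Mendelian transmission from two parents in the same sampling group.
#'
#' @param demog a \code{\link{demography}} whose sampled demes are the
#'   clusters; group frequencies are generated for every entry of
#'   \code{groups}.
#' @param groups data.frame with columns \code{group}, \code{cluster},
#'   \code{n} (diploid individuals).
#' @param n_sites number of biallelic SNP sites.
#' @param missing_rate per-genotype missing probability for ordinary
#'   individuals.
#' @param relative_pairs number of planted parent-offspring pairs.
#' @param low_quality number of planted low-quality individuals (mean depth
#'   < 4 or missingness > 0.30).
#' @param site_fail_rate fraction of sites drawn from the failing QC
#'   annotation mixture.
#' @param group_fst Balding-Nichols divergence of groups around their
#'   cluster frequency.
#' @param freq_haploids haploid lineages per cluster used for the frequency
#'   simulation.
#' @param n_genealogies distinct genealogies behind the site frequencies.
#' @param seed integer root seed.
#' @return a list of class \code{genotype_cohort}: \code{geno} (individuals x
#'   sites, 0/1/2/NA), \code{sites} (per-site annotations and true QC
#'   labels), \code{individuals} (group, cluster, mean depth, missingness,
#'   truth flags), \code{pop_map}, \code{relatives} (planted pairs).
#' @export
simulate_genotype_matrix <- function(demog, groups, n_sites = 5000,
                                     missing_rate = 0.02, relative_pairs = 0,
                                     low_quality = 0, site_fail_rate = 0.05,
                                     group_fst = 0.05, freq_haploids = 40,
                                     n_genealogies = 1000, seed = 1) {
  stopifnot(inherits(demog, "demography"), is.data.frame(groups),
            all(c("group", "cluster", "n") %in% names(groups)))
  clusters <- .sampled_pops(demog)
  bad <- setdiff(groups$cluster, clusters)
  if (length(bad)) stop("group cluster label absent from demography: ",
                        paste(bad, collapse = ", "))
  set.seed(.seed_int(seed) %% .Machine$integer.max)
  fd <- demog
  fd$demes$n_samples <- ifelse(fd$demes$n_samples > 0, freq_haploids, 0L)
  cnt <- cpp_conditional_sites(.demog_cpp(fd), as.integer(n_sites),
                               as.integer(n_genealogies), .seed_int(seed))
  freq_cluster <- cnt / freq_haploids          # n_sites x n_clusters
  colnames(freq_cluster) <- clusters

  ng <- nrow(groups)
  ind <- data.frame(
    id = unlist(lapply(seq_len(ng), function(i)
      sprintf("%s_%02d", groups$group[i], seq_len(groups$n[i])))),
    group = rep(groups$group, groups$n),
    cluster = rep(groups$cluster, groups$n),
    stringsAsFactors = FALSE)
  n_ind <- nrow(ind)

  # group-level Balding-Nichols deviation around the cluster frequency
  geno <- matrix(NA_integer_, n_ind, n_sites,
                 dimnames = list(ind$id, sprintf("site%05d", seq_len(n_sites))))
  for (gi in seq_len(ng)) {
    p0 <- pmin(pmax(freq_cluster[, groups$cluster[gi]], 1e-4), 1 - 1e-4)
    if (group_fst > 0) {
      a <- p0 * (1 - group_fst) / group_fst
      b <- (1 - p0) * (1 - group_fst) / group_fst
      pg <- rbeta(n_sites, a, b)
    } else pg <- p0
    rows <- which(ind$group == groups$group[gi])
    for (r in rows) geno[r, ] <- rbinom(n_sites, 2L, pg)
  }

  # planted parent-offspring pairs: overwrite a third individual of the same
  # group as the Mendelian child of two others
  relatives <- data.frame(parent = character(), child = character())
  if (relative_pairs > 0) {
    eligible <- groups$group[groups$n >= 3]
    if (length(eligible) == 0) stop("relative_pairs needs a group with >= 3 individuals")
    for (k in seq_len(relative_pairs)) {
      gname <- eligible[(k - 1) %% length(eligible) + 1]
      rows <- which(ind$group == gname)
      trio <- rows[((3 * (k - 1)) %% (length(rows) - 2)) + c(1, 2, 3)]
      pa <- geno[trio[1], ]; ma <- geno[trio[2], ]
      transmit <- function(g) ifelse(g == 0L, 0L,
                              ifelse(g == 2L, 1L, rbinom(n_sites, 1L, 0.5)))
      geno[trio[3], ] <- transmit(pa) + transmit(ma)
      relatives <- rbind(relatives,
                         data.frame(parent = ind$id[trio[1]],
                                    child = ind$id[trio[3]]))
    }
  }

  # planted low-quality individuals: depth < 4 and/or missingness > 0.30
  ind$true_low_quality <- FALSE
  ind$mean_depth <- pmax(4.2, stats::rnorm(n_ind, 25, 8))
  miss_p <- rep(missing_rate, n_ind)
  if (low_quality > 0) {
    lw <- sample(setdiff(seq_len(n_ind),
                         match(c(relatives$parent, relatives$child), ind$id)),
                 low_quality)
    ind$true_low_quality[lw] <- TRUE
    half <- lw[seq_len(ceiling(length(lw) / 2))]
    ind$mean_depth[half] <- runif(length(half), 1, 3.9)
    miss_p[setdiff(lw, half)] <- runif(length(setdiff(lw, half)), 0.35, 0.7)
  }
  for (r in seq_len(n_ind)) {
    nm <- rbinom(1, n_sites, miss_p[r])
    if (nm > 0) geno[r, sample.int(n_sites, nm)] <- NA_integer_
  }
  ind$missing_rate <- rowMeans(is.na(geno))

  # per-site QC annotations from pass/fail mixtures with known labels
  fail <- runif(n_sites) < site_fail_rate
  rtrunc <- function(n, mean, sd, lo, hi) pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
  sites <- data.frame(
    chrom = paste0("chr", 1 + (seq_len(n_sites) - 1) %/% ceiling(n_sites / 20)),
    pos = 1000L + 4000L * ((seq_len(n_sites) - 1) %% ceiling(n_sites / 20)),
    id = colnames(geno),
    ref = "A", alt = "G",
    QUAL = ifelse(fail, rtrunc(n_sites, 45, 10, 5, 59.9),
                  rtrunc(n_sites, 500, 150, 60.5, 5000)),
    FS = ifelse(fail, rtrunc(n_sites, 70, 10, 60.1, 200),
                rtrunc(n_sites, 5, 5, 0, 59.5)),
    QD = ifelse(fail, rtrunc(n_sites, 1.2, 0.5, 0.01, 1.99),
                rtrunc(n_sites, 20, 6, 2.01, 40)),
    MQ = ifelse(fail, rtrunc(n_sites, 30, 6, 5, 39.9),
                rtrunc(n_sites, 58, 2, 40.1, 60)),
    MQRankSum = rtrunc(n_sites, 0, 1.5, -19, 19),
    ReadPosRankSum = rtrunc(n_sites, 0, 1.5, -7.5, 7.5),
    true_fail = fail,
    stringsAsFactors = FALSE)
  # a failing site always fails QUAL; each other rule reverts to a passing
  # draw with probability 1/2 so failures trip varying rule subsets
  revert <- function(col, pass_vals) {
    r <- fail & runif(n_sites) < 0.5
    col[r] <- pass_vals[r]
    col
  }
  sites$FS <- revert(sites$FS, rtrunc(n_sites, 5, 5, 0, 59.5))
  sites$QD <- revert(sites$QD, rtrunc(n_sites, 20, 6, 2.01, 40))
  sites$MQ <- revert(sites$MQ, rtrunc(n_sites, 58, 2, 40.1, 60))

  pop_map <- setNames(ind$cluster, ind$id)
  structure(list(geno = geno, sites = sites, individuals = ind,
                 pop_map = pop_map,
                 group_map = setNames(ind$group, ind$id),
                 relatives = relatives, seed = seed),
            class = "genotype_cohort")
}

#' Default synthetic cohort design: 20 sampling groups in 5 clusters
#'
#' Mirrors the study's sampling layout: 20 groups (SE a single isolated
#' group), 494 collected individuals by default, of which 164 are planted as
#' low-quality and 21 as first-degree relatives, so the QC and kinship stages
#' have ground truth to recover.
#'
#' @param total total diploid individuals across groups.
#' @return data.frame with columns \code{group}, \code{cluster}, \code{n}.
#' @export
default_group_design <- function(total = 494) {
  cl <- c(rep("SW", 4), "SE", rep("C", 6), rep("NC", 5), rep("N", 4))
  ng <- length(cl)
  n <- rep(total %/% ng, ng)
  n[seq_len(total %% ng)] <- n[seq_len(total %% ng)] + 1L
  data.frame(group = sprintf("G%02d_%s", seq_len(ng), cl), cluster = cl, n = n)
}
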
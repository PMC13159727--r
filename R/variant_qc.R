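#' Default site hard-filter thresholds
#'
#' Removal conditions are stated as strict inequalities (a site is removed if
#' QUAL < 60, FS > 60, QD < 2, MQ < 40, MQRankSum < -20, ReadPosRankSum < -8,
#' MAF < 0.05, or missingness > \code{max_site_missing}); values exactly at a
#' threshold pass. \code{max_site_missing = 0.20} reads the "missing in >
#' 80\% of samples" rule as a call-rate requirement of 80\%; set it to 0.80
#' for the literal reading.
#'
#' @return named list of thresholds.
#' @export
default_site_thresholds <- function() {
  list(min_qual = 60, max_fs = 60, min_qd = 2, min_mq = 40,
       min_mqranksum = -20, min_readposranksum = -8, min_maf = 0.05,
       max_site_missing = 0.20)
}

# rule order fixes first-failure attribution in the report
.SITE_RULES <- c("nonbiallelic", "QUAL", "FS", "QD", "MQ", "MQRankSum",
                 "ReadPosRankSum", "MAF", "site_missingness")

#' Apply hard filters to SNP site records
#'
#' A site is removed if it fails any rule; the report attributes each removal
#' to the first failing rule in the documented order (nonbiallelic, QUAL, FS,
#' QD, MQ, MQRankSum, ReadPosRankSum, MAF, site missingness). A missing
#' annotation skips that rule for that record (GATK emits rank-sum statistics
#' only for sites with heterozygous carriers); skips are counted in the
#' report.
#'
#' @param sites data.frame of per-site records with (any of) columns
#'   \code{QUAL}, \code{FS}, \code{QD}, \code{MQ}, \code{MQRankSum},
#'   \code{ReadPosRankSum}, and optionally \code{biallelic} (logical),
#'   \code{maf}, \code{missingness}. MAF/missingness can also be computed
#'   from \code{geno} (individuals x sites).
#' @param thresholds list as from \code{\link{default_site_thresholds}}.
#' @param geno optional genotype matrix used to compute per-site MAF and
#'   missingness when those columns are absent.
#' @return list with \code{sites} (kept records), \code{kept} (logical
#'   vector over input sites) and \code{report} (a \code{filter_report}).
#' @export
filter_sites <- function(sites, thresholds = default_site_thresholds(),
                         geno = NULL) {
  stopifnot(is.data.frame(sites))
  n <- nrow(sites)
  th <- modifyList(default_site_thresholds(), as.list(thresholds))
  if (!is.null(geno)) {
    stopifnot(ncol(geno) == n)
    if (is.null(sites$missingness)) sites$missingness <- colMeans(is.na(geno))
    if (is.null(sites$maf)) {
      p <- colMeans(geno, na.rm = TRUE) / 2
      sites$maf <- pmin(p, 1 - p)
    }
  }
  fails <- list(
    nonbiallelic = if (!is.null(sites$biallelic)) !sites$biallelic else rep(FALSE, n),
    QUAL = sites$QUAL < th$min_qual,
    FS = sites$FS > th$max_fs,
    QD = sites$QD < th$min_qd,
    MQ = sites$MQ < th$min_mq,
    MQRankSum = sites$MQRankSum < th$min_mqranksum,
    ReadPosRankSum = sites$ReadPosRankSum < th$min_readposranksum,
    MAF = sites$maf < th$min_maf,
    site_missingness = sites$missingness > th$max_site_missing)
  skipped <- integer(0)
  for (r in .SITE_RULES) {
    f <- fails[[r]]
    if (is.null(f)) f <- rep(FALSE, n)
    if (length(f) == 0) f <- rep(NA, n)  # annotation column absent entirely
    skipped[r] <- sum(is.na(f))
    f[is.na(f)] <- FALSE
    fails[[r]] <- f
  }
  fail_mat <- do.call(cbind, fails[.SITE_RULES])
  first_fail <- apply(fail_mat, 1, function(x) which(x)[1])
  kept <- is.na(first_fail)
  removed <- table(factor(.SITE_RULES[first_fail[!kept]], levels = .SITE_RULES))
  report <- structure(list(
    stage = "filter_sites",
    n_input = n, n_kept = sum(kept),
    removed_by_rule = as.list(removed),
    skipped_missing_annotation = as.list(skipped[skipped > 0]),
    thresholds = th), class = "filter_report")
  list(sites = sites[kept, , drop = FALSE], kept = kept, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter report [", x$stage, "]: ", x$n_input, " -> ", x$n_kept, "\n",
      sep = "")
  for (r in names(x$removed_by_rule))
    if (x$removed_by_rule[[r]] > 0)
      cat(sprintf("  %-18s removed %d\n", r, x$removed_by_rule[[r]]))
  invisible(x)
}

#' Filter individuals on depth and missingness
#'
#' An individual is removed iff mean depth < \code{min_mean_depth} or missing
#' fraction > \code{max_missing} (boundaries pass).
#'
#' @param individuals data.frame with columns \code{id}, \code{mean_depth},
#'   \code{missing_rate}.
#' @param min_mean_depth,max_missing thresholds (defaults 4x and 0.30).
#' @return list with \code{kept} (character ids), \code{removed}, and
#'   \code{report}.
#' @export
filter_individuals <- function(individuals, min_mean_depth = 4,
                               max_missing = 0.30) {
  stopifnot(all(c("id", "mean_depth", "missing_rate") %in% names(individuals)))
  low_depth <- individuals$mean_depth < min_mean_depth
  high_miss <- individuals$missing_rate > max_missing
  drop <- low_depth | high_miss
  report <- structure(list(
    stage = "filter_individuals",
    n_input = nrow(individuals), n_kept = sum(!drop),
    removed_by_rule = list(low_depth = sum(low_depth),
                           high_missingness = sum(high_miss & !low_depth)),
    thresholds = list(min_mean_depth = min_mean_depth,
                      max_missing = max_missing)), class = "filter_report")
  list(kept = individuals$id[!drop], removed = individuals$id[drop],
       report = report)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on genotype counts: conditional on the allele counts,
#' the p-value is the summed probability of every heterozygote count whose
#' conditional (Levene) probability does not exceed that of the observed
#' count.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("no genotypes")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  rare <- min(nA, na)
  hets <- seq(rare %% 2, rare, by = 2)     # attainable heterozygote counts
  # log conditional probability of n_Aa hets given allele counts (Levene)
  logp <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- (n - h - hom_r)
    h * log(2) + lfactorial(n) - lfactorial(h) - lfactorial(hom_r) -
      lfactorial(hom_c) + lfactorial(nA) + lfactorial(na) -
      lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  if (is.na(obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' KING-robust pairwise kinship
#'
#' Between-family KING-robust estimator over pairwise-complete sites:
#' \deqn{\phi = (N_{Aa,Aa} - 2 N_{AA,aa}) / (N_{Aa}(i) + N_{Aa}(j))}
#' where \eqn{N_{Aa,Aa}} counts double heterozygotes, \eqn{N_{AA,aa}}
#' opposite homozygotes, and \eqn{N_{Aa}(.)} the per-individual heterozygote
#' totals, all restricted to sites non-missing in both individuals. Expected
#' values: 0.5 for duplicates/MZ twins, 0.25 for parent-offspring, ~0 for
#' unrelated individuals; > 0.177 flags first-degree relatives. Pairs with no
#' overlapping sites get NA.
#'
#' @param geno individuals x sites genotype matrix (0/1/2/NA) with rownames.
#' @return symmetric kinship matrix with 0.5 on the diagonal.
#' @export
king_kinship <- function(geno) {
  stopifnot(is.matrix(geno))
  het <- (geno == 1L); het[is.na(het)] <- FALSE
  aa0 <- (geno == 0L); aa0[is.na(aa0)] <- FALSE
  aa2 <- (geno == 2L); aa2[is.na(aa2)] <- FALSE
  obs <- !is.na(geno)
  storage.mode(het) <- "double"; storage.mode(aa0) <- "double"
  storage.mode(aa2) <- "double"; storage.mode(obs) <- "double"
  n_hh <- tcrossprod(het)                       # double heterozygotes
  n_opp <- tcrossprod(aa0, aa2)
  n_opp <- n_opp + t(n_opp)                     # opposite homozygotes
  het_i <- tcrossprod(het, obs)                 # i het & j observed
  denom <- het_i + t(het_i)
  overlap <- tcrossprod(obs)
  phi <- (n_hh - 2 * n_opp) / denom
  phi[overlap == 0] <- NA_real_
  phi[denom == 0 & overlap > 0] <- 0
  diag(phi) <- 0.5
  dimnames(phi) <- list(rownames(geno), rownames(geno))
  phi
}

#' Prune individuals until no first-degree pair remains
#'
#' Greedy minimal vertex cover on the graph of pairs with kinship above the
#' threshold: repeatedly remove the individual incident to the most flagged
#' pairs, breaking ties by higher missingness then label order.
#'
#' @param K kinship matrix (as from \code{\link{king_kinship}}).
#' @param threshold kinship cutoff (default 0.177, the first-degree bound).
#' @param missingness optional named vector used for tie-breaking.
#' @return list with \code{kept} and \code{removed} id vectors.
#' @export
prune_first_degree <- function(K, threshold = 0.177, missingness = NULL) {
  ids <- rownames(K)
  A <- !is.na(K) & K > threshold
  diag(A) <- FALSE
  removed <- character(0)
  while (any(A)) {
    deg <- rowSums(A)
    cand <- which(deg == max(deg))
    if (length(cand) > 1 && !is.null(missingness)) {
      mr <- missingness[ids[cand]]
      cand <- cand[order(-mr, ids[cand])]
    }
    v <- cand[1]
    removed <- c(removed, ids[v])
    A[v, ] <- FALSE
    A[, v] <- FALSE
  }
  list(kept = setdiff(ids, removed), removed = removed)
}

# merge possibly-overlapping 0-based half-open intervals per chromosome
.merge_intervals <- function(bed) {
  if (nrow(bed) == 0) return(bed)
  out <- do.call(rbind, lapply(split(bed, bed$chrom), function(b) {
    b <- b[order(b$start), , drop = FALSE]
    merged <- b[1, , drop = FALSE]
    for (i in seq_len(nrow(b))[-1]) {
      last <- nrow(merged)
      if (b$start[i] <= merged$end[last]) {
        merged$end[last] <- max(merged$end[last], b$end[i])
      } else merged <- rbind(merged, b[i, , drop = FALSE])
    }
    merged
  }))
  rownames(out) <- NULL
  out
}

.in_mask <- function(chrom, pos, bed) {
  if (is.null(bed) || nrow(bed) == 0) return(rep(FALSE, length(pos)))
  hit <- rep(FALSE, length(pos))
  for (ch in unique(bed$chrom)) {
    b <- bed[bed$chrom == ch, , drop = FALSE]
    sel <- chrom == ch
    if (!any(sel)) next
    # BED 0-based half-open [start, end) vs 1-based positions
    for (i in seq_len(nrow(b)))
      hit[sel] <- hit[sel] | (pos[sel] > b$start[i] & pos[sel] <= b$end[i])
  }
  hit
}

#' Design a neutral SNP panel
#'
#' Applies, in order: autosomal-biallelic restriction, gene-mask exclusion,
#' CpG-island-mask exclusion, complete-genotyping requirement, minor allele
#' frequency >= \code{maf_min}, exact Hardy-Weinberg p >= \code{hwe_alpha},
#' then per-chromosome thinning keeping the first surviving SNP of each
#' \code{thin_bp} window (windows anchored at position 1).
#'
#' @param sites data.frame with columns \code{chrom}, \code{pos} (1-based)
#'   and optionally \code{biallelic}, \code{autosomal}.
#' @param geno genotype matrix (individuals x sites) aligned with
#'   \code{sites}; used for the call-rate, MAF and HWE rules.
#' @param gene_mask,cpg_mask data.frames of 0-based half-open intervals
#'   (\code{chrom}, \code{start}, \code{end}); overlapping intervals are
#'   merged.
#' @param maf_min,hwe_alpha,thin_bp panel thresholds (defaults 0.05, 0.001,
#'   10000).
#' @return list with \code{panel} (kept site rows), \code{kept} (logical) and
#'   \code{report}.
#' @export
design_panel <- function(sites, geno, gene_mask = NULL, cpg_mask = NULL,
                         maf_min = 0.05, hwe_alpha = 0.001, thin_bp = 10000) {
  n <- nrow(sites)
  stopifnot(ncol(geno) == n)
  if (!is.null(gene_mask)) gene_mask <- .merge_intervals(gene_mask)
  if (!is.null(cpg_mask)) cpg_mask <- .merge_intervals(cpg_mask)
  steps <- list()
  alive <- rep(TRUE, n)
  drop_step <- function(alive, bad, label) {
    steps[[label]] <<- sum(alive & bad)
    alive & !bad
  }
  nonbi <- if (!is.null(sites$biallelic)) !sites$biallelic else rep(FALSE, n)
  nonauto <- if (!is.null(sites$autosomal)) !sites$autosomal else
    grepl("chr[XY]", sites$chrom)
  alive <- drop_step(alive, nonbi | nonauto, "non_biallelic_autosomal")
  alive <- drop_step(alive, .in_mask(sites$chrom, sites$pos, gene_mask), "gene_mask")
  alive <- drop_step(alive, .in_mask(sites$chrom, sites$pos, cpg_mask), "cpg_mask")
  alive <- drop_step(alive, colSums(is.na(geno)) > 0, "incomplete_genotyping")
  p <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  alive <- drop_step(alive, is.na(maf) | maf < maf_min, "maf")
  hwe_p <- rep(NA_real_, n)
  for (j in which(alive)) {
    g <- geno[, j]
    hwe_p[j] <- hwe_exact_test(sum(g == 0, na.rm = TRUE),
                               sum(g == 1, na.rm = TRUE),
                               sum(g == 2, na.rm = TRUE))
  }
  alive <- drop_step(alive, !is.na(hwe_p) & hwe_p < hwe_alpha, "hwe")
  # thinning: first surviving SNP per thin_bp window per chromosome
  thin_drop <- rep(FALSE, n)
  idx <- which(alive)
  win <- paste(sites$chrom[idx], (sites$pos[idx] - 1) %/% thin_bp)
  ord <- idx[order(sites$chrom[idx], sites$pos[idx])]
  win_ord <- paste(sites$chrom[ord], (sites$pos[ord] - 1) %/% thin_bp)
  thin_drop[ord[duplicated(win_ord)]] <- TRUE
  alive <- drop_step(alive, thin_drop, "thin_10kb")
  report <- structure(list(stage = "design_panel", n_input = n,
                           n_kept = sum(alive), removed_by_rule = steps,
                           thresholds = list(maf_min = maf_min,
                                             hwe_alpha = hwe_alpha,
                                             thin_bp = thin_bp)),
                      class = "filter_report")
  list(panel = sites[alive, , drop = FALSE], kept = alive, report = report)
}
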
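#' Per-individual observed heterozygosity
#'
#' Ho = heterozygous calls / non-missing calls for each individual.
#'
#' @param geno individuals x sites genotype matrix (0/1/2/NA).
#' @return named numeric vector in [0, 1].
#' @export
observed_heterozygosity <- function(geno) {
  nonmiss <- rowSums(!is.na(geno))
  if (any(nonmiss == 0))
    stop("individual(s) with all genotypes missing: ",
         paste(rownames(geno)[nonmiss == 0], collapse = ", "))
  het <- rowSums(geno == 1L, na.rm = TRUE)
  setNames(het / nonmiss, rownames(geno))
}

# Weir & Cockerham (1984) per-locus variance components for one site.
# Returns c(a, a+b+c); multilocus theta = sum(a) / sum(a+b+c).
.wc_components <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 2 || n2 < 2) return(c(0, 0))
  r <- 2
  p1 <- mean(g1) / 2; p2 <- mean(g2) / 2
  h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a, a + b + cc)
}

#' Pairwise multilocus Weir-Cockerham F_ST
#'
#' Ratio-of-averages WC84 estimator between every pair of populations:
#' per-locus variance components are summed over loci before taking the
#' ratio. Estimates can be slightly negative for undifferentiated pairs and
#' are reported as computed (clamping happens only at linearization).
#'
#' @param geno individuals x sites genotype matrix (0/1/2/NA) with rownames.
#' @param pop_map named vector mapping individual id -> population.
#' @param populations populations to compare (default: all in
#'   \code{pop_map}, sorted).
#' @return symmetric matrix of F_ST with zero diagonal.
#' @export
pairwise_fst <- function(geno, pop_map,
                         populations = sort(unique(unname(pop_map)))) {
  ids <- rownames(geno)
  counts <- table(factor(unname(pop_map[ids]), levels = populations))
  if (any(counts < 2))
    stop("population(s) with < 2 individuals: ",
         paste(populations[counts < 2], collapse = ", "))
  k <- length(populations)
  out <- matrix(0, k, k, dimnames = list(populations, populations))
  # per-population, per-site summaries (vectorized over sites)
  summ <- lapply(populations, function(p) {
    g <- geno[unname(pop_map[ids]) == p, , drop = FALSE]
    nn <- colSums(!is.na(g))
    list(n = nn, p = colSums(g, na.rm = TRUE) / (2 * pmax(nn, 1)),
         h = colSums(g == 1L, na.rm = TRUE) / pmax(nn, 1))
  })
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    s1 <- summ[[i]]; s2 <- summ[[j]]
    use <- s1$n >= 2 & s2$n >= 2
    n1 <- s1$n[use]; n2 <- s2$n[use]
    p1 <- s1$p[use]; p2 <- s2$p[use]
    h1 <- s1$h[use]; h2 <- s2$h[use]
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2v <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- nbar / nc * (s2v - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2v - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2v -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    denom <- sum(a + b + cc)
    out[i, j] <- out[j, i] <- if (denom > 0) sum(a) / denom else NA_real_
  }
  out
}

#' Linearize F_ST to a genetic distance
#'
#' Rousset's transform f / (1 - f); negative estimates are clamped to 0
#' first, and f = 1 is rejected (infinite distance).
#'
#' @param f F_ST value(s) or a matrix.
#' @return transformed value(s), same shape.
#' @export
linearize_fst <- function(f) {
  if (any(f >= 1, na.rm = TRUE)) stop("F_ST = 1 gives infinite genetic distance")
  f <- pmax(f, 0)
  out <- f / (1 - f)
  if (is.matrix(f)) diag(out) <- 0
  out
}

#' Great-circle geographic distance matrix (km)
#'
#' Haversine distances between labelled coordinates.
#'
#' @param coords data.frame with columns \code{label}, \code{lat},
#'   \code{lon} (decimal degrees).
#' @return symmetric distance matrix in km with zero diagonal.
#' @export
geographic_distances <- function(coords) {
  stopifnot(all(c("label", "lat", "lon") %in% names(coords)))
  if (any(abs(coords$lat) > 90) || any(abs(coords$lon) > 180))
    stop("coordinates out of range")
  # mean Earth radius 6371 km (classic haversine constant)
  m <- geosphere::distm(coords[, c("lon", "lat")],
                        fun = function(a, b)
                          geosphere::distHaversine(a, b, r = 6371000)) / 1000
  dimnames(m) <- list(coords$label, coords$label)
  m
}

#' Mantel test of matrix association
#'
#' One-sided permutation test of the Pearson correlation between the
#' off-diagonal upper triangles of two labelled distance matrices (the
#' isolation-by-distance test when applied to linearized F_ST vs geographic
#' distance). Row/column labels of the second matrix are permuted jointly;
#' p = (1 + #\{permuted r >= observed r\}) / (n_perm + 1).
#'
#' @param d_gen,d_geo symmetric matrices with matching dimnames.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed for the permutation stream.
#' @return list with \code{r}, \code{r_squared}, \code{p}, \code{n_perm}.
#' @export
mantel_test <- function(d_gen, d_geo, n_perm = 999, seed = 1) {
  stopifnot(n_perm >= 99)
  labs <- rownames(d_gen)
  if (!identical(sort(labs), sort(rownames(d_geo))))
    stop("matrix labels do not match")
  d_geo <- d_geo[labs, labs]
  ut <- upper.tri(d_gen)
  x <- d_gen[ut]
  if (stats::sd(x) == 0 || stats::sd(d_geo[ut]) == 0)
    stop("constant distance matrix: correlation undefined")
  r_obs <- stats::cor(x, d_geo[ut])
  n <- length(labs)
  set.seed(.seed_int(seed) %% .Machine$integer.max)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    r_b <- stats::cor(x, d_geo[perm, perm][ut])
    if (r_b >= r_obs - 1e-12) hits <- hits + 1L
  }
  p <- (1 + hits) / (n_perm + 1)
  list(r = r_obs, r_squared = r_obs^2, p = p, n_perm = n_perm)
}

#' Exhaustive Mantel test over all label permutations
#'
#' Reference version for small matrices (<= 8 labels): enumerates every
#' permutation; p = #\{r_perm >= r_obs\} / n!. Used to validate the
#' permutation sampler.
#'
#' @param d_gen,d_geo symmetric matrices with matching dimnames.
#' @return list with \code{r}, \code{p}.
#' @export
mantel_test_exact <- function(d_gen, d_geo) {
  labs <- rownames(d_gen)
  n <- length(labs)
  if (n > 8) stop("exhaustive enumeration limited to 8 labels")
  d_geo <- d_geo[labs, labs]
  ut <- upper.tri(d_gen)
  x <- d_gen[ut]
  r_obs <- stats::cor(x, d_geo[ut])
  perms <- .permutations(n)
  rs <- apply(perms, 1, function(p) stats::cor(x, d_geo[p, p][ut]))
  list(r = r_obs, p = mean(rs >= r_obs - 1e-12))
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, ifelse(sub >= i, sub + 1L, sub))))
}
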
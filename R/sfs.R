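#' Site frequency spectrum container
#'
#' A (joint) SFS is an array of site counts indexed by the number of derived
#' (or minor, if folded) allele copies in each population: axis \code{k} has
#' length \code{n_k + 1} where \code{n_k} is the haploid sample size. Entries
#' are non-negative reals (projection produces fractional expectations). The
#' two monomorphic corner cells are kept in the array but reported separately
#' by consumers; composite likelihoods exclude them by default.
#'
#' @param counts numeric array (or vector for 1 population).
#' @param pops character vector of population labels, one per axis.
#' @param folded logical; TRUE if indexed by minor-allele counts.
#' @return object of class \code{sfs}.
#' @export
sfs <- function(counts, pops, folded = FALSE) {
  if (is.null(dim(counts))) counts <- array(counts, dim = length(counts))
  stopifnot(length(pops) == length(dim(counts)), all(counts >= 0) || all(is.na(counts)))
  structure(list(counts = counts, pops = as.character(pops),
                 folded = isTRUE(folded)),
            class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat("joint SFS over", paste(x$pops, collapse = ", "), "| dims",
      paste(dim(x$counts), collapse = " x "), "|",
      if (x$folded) "folded" else "unfolded", "\n")
  cat("  polymorphic mass:", format(sum(polymorphic_mask(x) * x$counts)),
      " monomorphic mass:", format(sum((!polymorphic_mask(x)) * x$counts)), "\n")
  invisible(x)
}

#' Haploid sample sizes per axis of an SFS
#' @param x an \code{sfs}.
#' @return integer vector.
#' @export
sample_sizes <- function(x) dim(x$counts) - 1L

#' Logical mask of polymorphic cells (excludes the all-zero and, for unfolded
#' spectra, the all-fixed corner).
#' @param x an \code{sfs}.
#' @return logical array matching \code{x$counts}.
#' @export
polymorphic_mask <- function(x) {
  d <- dim(x$counts)
  mask <- array(TRUE, dim = d)
  mask[matrix(1L, 1, length(d))] <- FALSE            # all-zero corner
  mask[matrix(d, 1, length(d))] <- FALSE             # all-fixed corner
  mask
}

#' Tabulate the joint SFS of a genotype matrix
#'
#' Each biallelic site increments the cell indexed by the per-population
#' alternate-allele count (minor-allele count if \code{folded}). Sites with
#' any missing genotype among the selected individuals are dropped
#' (complete-case per site). Sites monomorphic in the selected sample land in
#' the corner cells.
#'
#' @param geno integer matrix, individuals x sites, genotypes 0/1/2/NA.
#' @param pop_map named character vector mapping individual id -> population.
#' @param populations populations to include, in axis order.
#' @param folded fold to minor-allele counts (default TRUE: no outgroup
#'   polarization for SNP-panel data).
#' @return an \code{sfs}; attribute \code{n_dropped_missing} counts
#'   complete-case-dropped sites.
#' @export
joint_sfs <- function(geno, pop_map, populations = sort(unique(pop_map)),
                      folded = TRUE) {
  ids <- rownames(geno)
  if (is.null(ids)) stop("genotype matrix must have individual ids as rownames")
  miss <- setdiff(ids, names(pop_map))
  if (length(miss)) stop("individuals missing from pop_map: ",
                         paste(head(miss, 5), collapse = ", "))
  keep <- ids[pop_map[ids] %in% populations]
  g <- geno[keep, , drop = FALSE]
  pops_i <- pop_map[keep]
  complete <- colSums(is.na(g)) == 0
  g <- g[, complete, drop = FALSE]
  n_hap <- unname(vapply(populations, function(p) 2L * sum(pops_i == p),
                         integer(1)))
  if (any(n_hap == 0)) stop("population with no individuals: ",
                            paste(populations[n_hap == 0], collapse = ", "))
  dims <- n_hap + 1L
  counts <- array(0, dim = dims)
  if (ncol(g)) {
    dac <- vapply(populations, function(p)
      colSums(g[pops_i == p, , drop = FALSE]), numeric(ncol(g)))
    dac <- matrix(dac, ncol = length(populations))
    if (folded) {
      tot <- rowSums(dac)
      flip <- tot > sum(n_hap) / 2 | (tot == sum(n_hap) / 2 & dac[, 1] > n_hap[1] / 2)
      dac[flip, ] <- rep(n_hap, each = sum(flip)) - dac[flip, , drop = FALSE]
    }
    idx <- as.integer(dac %*% cumprod(c(1, dims[-length(dims)]))) + 1L
    tab <- tabulate(idx, nbins = prod(dims))
    counts <- array(counts + tab, dim = dims)
  }
  out <- sfs(counts, populations, folded = folded)
  attr(out, "n_dropped_missing") <- sum(!complete)
  out
}

#' Fold an SFS to minor-allele counts
#'
#' Entry \code{i} of the folded spectrum is \code{unfolded[i] +
#' unfolded[n - i]} for \code{i < n/2} (total derived count over all axes),
#' with the half-count diagonal kept once.
#'
#' @param x an unfolded \code{sfs}.
#' @return folded \code{sfs} with identical dimensions.
#' @export
fold_sfs <- function(x) {
  if (x$folded) return(x)
  d <- dim(x$counts)
  n <- d - 1L
  ntot <- sum(n)
  grid <- as.matrix(expand.grid(lapply(n, function(k) 0:k)))
  tot <- rowSums(grid)
  out <- array(0, dim = d)
  v <- as.vector(x$counts)
  mirror_idx <- as.integer((rep(n, each = nrow(grid)) - grid) %*%
                             cumprod(c(1, d[-length(d)]))) + 1L
  keep <- tot < ntot / 2 | (tot == ntot / 2 & grid[, 1] <= n[1] / 2)
  out_v <- numeric(length(v))
  out_v[keep] <- v[keep] + ifelse(mirror_idx[keep] == seq_along(v)[keep], 0,
                                  v[mirror_idx[keep]])
  sfs(array(out_v, dim = d), x$pops, folded = TRUE)
}

# hypergeometric projection weight matrix: rows j = 0..n_to, cols d = 0..n_from
.proj_matrix <- function(n_from, n_to) {
  W <- outer(0:n_to, 0:n_from, function(j, d)
    exp(lchoose(d, j) + lchoose(n_from - d, n_to - j) - lchoose(n_from, n_to)))
  W[is.na(W)] <- 0
  W
}

#' Project an SFS to smaller sample sizes
#'
#' Hypergeometric (easySFS-style) projection: mass at derived count \code{d}
#' of \code{n} is redistributed to count \code{j} of \code{n'} with weight
#' \code{C(d,j) C(n-d, n'-j) / C(n, n')}. Total mass is conserved; projected
#' entries are fractional expectations.
#'
#' @param x an \code{sfs}.
#' @param target_sizes integer vector of target haploid sizes, one per axis.
#' @return projected \code{sfs}.
#' @export
project_sfs <- function(x, target_sizes) {
  n <- sample_sizes(x)
  stopifnot(length(target_sizes) == length(n))
  if (any(target_sizes > n)) stop("target size exceeds source size")
  a <- x$counts
  d <- dim(a)
  for (ax in seq_along(n)) {
    if (target_sizes[ax] == n[ax]) next
    W <- .proj_matrix(n[ax], target_sizes[ax])
    if (length(d) == 1) {
      a <- array(as.vector(W %*% as.vector(a)), dim = target_sizes[ax] + 1L)
    } else {
      a <- apply(a, setdiff(seq_along(d), ax), function(v) W %*% v)
      # apply puts the transformed axis first; restore original axis order
      dim(a) <- c(target_sizes[ax] + 1L, d[-ax])
      a <- aperm(a, order(c(ax, setdiff(seq_along(d), ax))))
    }
    d <- dim(a)
  }
  sfs(a, x$pops, folded = x$folded)
}

#' Marginalize a joint SFS onto a subset of populations
#'
#' Sums counts over the dropped axes; mass is conserved.
#'
#' @param x an \code{sfs}.
#' @param pops populations to keep (order defines the new axis order).
#' @return lower-dimensional \code{sfs}.
#' @export
marginalize_sfs <- function(x, pops) {
  if (length(pops) == 0) stop("empty population list")
  keep <- match(pops, x$pops)
  if (anyNA(keep)) stop("unknown population(s): ",
                        paste(pops[is.na(keep)], collapse = ", "))
  a <- apply(x$counts, keep, sum)
  if (is.null(dim(a))) a <- array(a, dim = length(a))
  sfs(a, x$pops[keep], folded = x$folded)
}

#' Read / write SFS files
#'
#' Two dialects: a flat JSON object (\code{dims}, \code{pops}, \code{folded},
#' \code{counts} in column-major order), and fastsimcoal-style
#' multidimensional text (header line \code{"1 observations"}, a dimension
#' line, then whitespace-separated counts in row-major order over the last
#' axis varying fastest).
#'
#' @param x an \code{sfs}.
#' @param path file path.
#' @param format \code{"json"} or \code{"fsc"}.
#' @return \code{read_sfs} returns an \code{sfs}; \code{write_sfs} returns
#'   \code{path} invisibly.
#' @export
write_sfs <- function(x, path, format = c("json", "fsc")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(list(pops = x$pops, dims = dim(x$counts),
                              folded = x$folded,
                              counts = as.vector(x$counts)),
                         path, auto_unbox = FALSE, digits = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("1 observations", con)
    writeLines(paste(c(length(x$pops), dim(x$counts), x$pops,
                       if (x$folded) "folded" else "unfolded"),
                     collapse = " "), con)
    # row-major: last axis varies fastest
    a <- aperm(x$counts, rev(seq_along(dim(x$counts))))
    writeLines(paste(format(as.vector(a), scientific = FALSE, trim = TRUE),
                     collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path, format = c("json", "fsc")) {
  format <- match.arg(format)
  if (format == "json") {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(sfs(array(j$counts, dim = j$dims), j$pops, folded = j$folded))
  }
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  k <- as.integer(hdr[1])
  dims <- as.integer(hdr[2:(1 + k)])
  pops <- hdr[(2 + k):(1 + 2 * k)]
  folded <- identical(hdr[2 + 2 * k], "folded")
  vals <- as.numeric(strsplit(trimws(lines[3]), "\\s+")[[1]])
  a <- aperm(array(vals, dim = rev(dims)), rev(seq_len(k)))
  sfs(a, pops, folded = folded)
}

#' Export 1D marginal spectra as TSV
#'
#' @param x an \code{sfs}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_sfs_marginals <- function(x, path) {
  rows <- do.call(rbind, lapply(x$pops, function(p) {
    m <- marginalize_sfs(x, p)
    data.frame(pop = p, allele_count = seq_along(as.vector(m$counts)) - 1L,
               sites = as.vector(m$counts))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
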
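#' Read a VCF into a genotype matrix and site records
#'
#' Reads a VCF 4.2 subset (biallelic SNPs, GT field, INFO keys FS, QD, MQ,
#' MQRankSum, ReadPosRankSum) via vcfR. Multiallelic records are dropped and
#' counted. Genotypes are coded as alternate-allele dosage 0/1/2 with NA for
#' missing.
#'
#' @param path VCF file (plain text or bgzipped).
#' @return list with \code{geno} (individuals x sites), \code{sites}
#'   (data.frame of chrom, pos, id, ref, alt, QUAL and INFO statistics) and
#'   \code{n_multiallelic_dropped}.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no records")
  multi <- grepl(",", fix$ALT)
  info_num <- function(key) {
    x <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
    if (length(x) == 0) rep(NA_real_, nrow(fix)) else x
  }
  sites <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID),
    ref = fix$REF, alt = fix$ALT,
    QUAL = suppressWarnings(as.numeric(fix$QUAL)),
    FS = info_num("FS"), QD = info_num("QD"), MQ = info_num("MQ"),
    MQRankSum = info_num("MQRankSum"),
    ReadPosRankSum = info_num("ReadPosRankSum"),
    biallelic = !multi,
    stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt))
  clean <- gsub("\\|", "/", gt)
  dose[clean %in% c("0/0")] <- 0L
  dose[clean %in% c("0/1", "1/0")] <- 1L
  dose[clean %in% c("1/1")] <- 2L
  keep <- !multi
  geno <- t(dose[keep, , drop = FALSE])
  rownames(geno) <- colnames(gt)
  colnames(geno) <- sites$id[keep]
  list(geno = geno, sites = sites[keep, , drop = FALSE],
       n_multiallelic_dropped = sum(multi))
}

#' Write a genotype matrix as a minimal VCF 4.2
#'
#' Inverse of \code{\link{read_vcf}} for the supported fields; the
#' write-then-read round trip is lossless for genotypes, positions, QUAL and
#' the INFO statistics.
#'
#' @param geno individuals x sites matrix (0/1/2/NA).
#' @param sites site data.frame (chrom, pos, id, ref, alt, QUAL, FS, QD, MQ,
#'   MQRankSum, ReadPosRankSum).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(geno, sites, path) {
  stopifnot(nrow(sites) == ncol(geno))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=rhinopop",
               '##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand">',
               '##INFO=<ID=QD,Number=1,Type=Float,Description="Qual by depth">',
               '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
               '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="MQ rank sum">',
               '##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="Read pos rank sum">',
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(geno)), collapse = "\t"), con)
  gt_code <- c("0/0", "0/1", "1/1")
  fmt <- function(x) formatC(x, format = "g", digits = 10)
  for (j in seq_len(nrow(sites))) {
    g <- geno[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    info <- paste0("FS=", fmt(sites$FS[j]), ";QD=", fmt(sites$QD[j]),
                   ";MQ=", fmt(sites$MQ[j]),
                   ";MQRankSum=", fmt(sites$MQRankSum[j]),
                   ";ReadPosRankSum=", fmt(sites$ReadPosRankSum[j]))
    writeLines(paste(c(sites$chrom[j], sites$pos[j], sites$id[j],
                       sites$ref[j], sites$alt[j], fmt(sites$QUAL[j]), ".",
                       info, "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a BED interval file (0-based half-open)
#'
#' Uses rtracklayer when available, falling back to a plain three-column
#' read. Coordinates are returned in BED convention (0-based half-open).
#'
#' @param path BED file.
#' @return data.frame with \code{chrom}, \code{start}, \code{end}.
#' @export
read_bed <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
    return(data.frame(chrom = as.character(gr$seqnames),
                      start = gr$start - 1L, end = gr$end,
                      stringsAsFactors = FALSE))
  }
  b <- read.table(path, sep = "\t", stringsAsFactors = FALSE)[, 1:3]
  names(b) <- c("chrom", "start", "end")
  b
}

#' Read a population map TSV (individual, group, cluster)
#'
#' @param path TSV with 2-3 columns: individual id, sampling group and
#'   optionally genetic cluster.
#' @return data.frame with \code{id}, \code{group}, \code{cluster}.
#' @export
read_popmap <- function(path) {
  x <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  names(x)[1:2] <- c("id", "group")
  if (ncol(x) < 3) x$cluster <- x$group else names(x)[3] <- "cluster"
  x
}

#' Read a coordinates TSV (label, lat, lon)
#' @param path TSV with header columns label, lat, lon.
#' @return data.frame.
#' @export
read_coords <- function(path) {
  x <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  names(x)[1:3] <- c("label", "lat", "lon")
  x
}

#' Write a labelled distance matrix as TSV
#' @param m matrix with dimnames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_distance_matrix <- function(m, path) {
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
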
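# deterministic synthetic geography: cluster centres in the species' range
# (NW Yunnan / SE Tibet), groups spread around their cluster centre
.CLUSTER_CENTRES <- data.frame(
  cluster = c("SW", "SE", "C", "NC", "N"),
  lat = c(26.2, 26.5, 27.5, 28.2, 28.9),
  lon = c(99.2, 99.6, 99.3, 99.0, 98.7))

.group_coords <- function(groups, seed) {
  set.seed(.derive_seed(seed, 31))
  ctr <- .CLUSTER_CENTRES[match(groups$cluster, .CLUSTER_CENTRES$cluster), ]
  data.frame(label = groups$group,
             lat = ctr$lat + runif(nrow(groups), -0.15, 0.15),
             lon = ctr$lon + runif(nrow(groups), -0.15, 0.15))
}

#' Build a validated pipeline configuration
#'
#' Stage toggles and thresholds default to the study's values (QUAL >= 60,
#' FS <= 60, QD >= 2, MQ >= 40, rank-sum bounds, MAF >= 0.05, individual
#' depth >= 4x and missingness <= 30\%, kinship cutoff 0.177, HWE alpha
#' 0.001, 10-kb thinning). All stochastic stages derive their seeds from the
#' single root \code{seed}. Unknown keys are rejected.
#'
#' @param seed root seed.
#' @param n_sites,total_individuals,relative_pairs,low_quality,missing_rate
#'   synthetic cohort size knobs (desk-scale defaults; see
#'   \code{\link{simulate_genotype_matrix}} for the full study-scale design).
#' @param stages named logical list toggling \code{qc}, \code{kinship},
#'   \code{panel}, \code{sfs}, \code{fit}, \code{stats}.
#' @param site_thresholds,kinship_threshold,min_mean_depth,max_missing,
#'   maf_min,hwe_alpha,thin_bp stage thresholds.
#' @param fit_n_sims,fit_cycles,fit_models,fit_diploids_per_cluster reduced
#'   model-fitting settings for the pipeline demonstration.
#' @param out_dir output directory.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(seed = 1, n_sites = 4000, total_individuals = 160,
                       relative_pairs = 5, low_quality = 15,
                       missing_rate = 0.02,
                       stages = list(), site_thresholds = list(),
                       kinship_threshold = 0.177, min_mean_depth = 4,
                       max_missing = 0.30, maf_min = 0.05, hwe_alpha = 0.001,
                       thin_bp = 10000, fit_n_sims = 400, fit_cycles = 1,
                       fit_models = c("model1_stepping", "model4_SE_NC_admix"),
                       fit_diploids_per_cluster = 5, out_dir = tempfile("run")) {
  default_stages <- list(qc = TRUE, kinship = TRUE, panel = TRUE, sfs = TRUE,
                         fit = TRUE, stats = TRUE)
  unknown <- setdiff(names(stages), names(default_stages))
  if (length(unknown)) stop("unknown stage toggle: ",
                            paste(unknown, collapse = ", "))
  unknown <- setdiff(names(site_thresholds), names(default_site_thresholds()))
  if (length(unknown)) stop("unknown site threshold: ",
                            paste(unknown, collapse = ", "))
  cfg <- list(seed = .seed_int(seed), n_sites = n_sites,
              total_individuals = total_individuals,
              relative_pairs = relative_pairs, low_quality = low_quality,
              missing_rate = missing_rate,
              stages = modifyList(default_stages, stages),
              site_thresholds = modifyList(default_site_thresholds(),
                                           site_thresholds),
              kinship_threshold = kinship_threshold,
              min_mean_depth = min_mean_depth, max_missing = max_missing,
              maf_min = maf_min, hwe_alpha = hwe_alpha, thin_bp = thin_bp,
              fit_n_sims = fit_n_sims, fit_cycles = fit_cycles,
              fit_models = fit_models,
              fit_diploids_per_cluster = fit_diploids_per_cluster,
              out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

.write_json <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

#' Run the full synthetic pipeline
#'
#' Orders the study's stages over a synthetic cohort: cohort simulation
#' under the best-fit five-cluster admixture demography, site and individual
#' QC, KING kinship pruning, neutral-panel design, joint SFS construction,
#' reduced-scale model fitting with AIC comparison, and the population
#' statistics (per-individual Ho, pairwise cluster and group F_ST, linearized
#' genetic distance, haversine geographic distance, Mantel IBD test).
#' Deterministic given \code{config$seed}; every stage writes JSON/TSV
#' results plus a manifest of seeds, thresholds and per-stage counts.
#'
#' @param config a \code{\link{run_config}}.
#' @param cohort optionally, a pre-built \code{genotype_cohort} (otherwise
#'   simulated from the config).
#' @return invisible list with all stage results and output paths.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list(package_version = as.character(utils::packageVersion("rhinopop")),
                   seed = config$seed,
                   thresholds = config[c("site_thresholds", "kinship_threshold",
                                         "min_mean_depth", "max_missing",
                                         "maf_min", "hwe_alpha", "thin_bp")],
                   stages = config$stages, counts = list())
  res <- list(config = config)

  # --- simulate ------------------------------------------------------------
  if (is.null(cohort)) {
    demog <- build_named_model("model4_SE_NC_admix")
    groups <- default_group_design(config$total_individuals)
    cohort <- simulate_genotype_matrix(
      demog, groups, n_sites = config$n_sites,
      missing_rate = config$missing_rate,
      relative_pairs = config$relative_pairs,
      low_quality = config$low_quality,
      seed = .derive_seed(config$seed, 1))
  }
  res$cohort <- cohort
  geno <- cohort$geno
  manifest$counts$simulated <- list(individuals = nrow(geno),
                                    sites = ncol(geno),
                                    planted_relative_pairs = nrow(cohort$relatives),
                                    planted_low_quality = sum(cohort$individuals$true_low_quality))

  # --- qc ------------------------------------------------------------------
  if (config$stages$qc) {
    fs <- filter_sites(cohort$sites, config$site_thresholds, geno = geno)
    geno <- geno[, fs$kept, drop = FALSE]
    fi <- filter_individuals(cohort$individuals,
                             min_mean_depth = config$min_mean_depth,
                             max_missing = config$max_missing)
    geno <- geno[rownames(geno) %in% fi$kept, , drop = FALSE]
    res$site_filter <- fs$report
    res$individual_filter <- fi$report
    .write_json(list(sites = unclass(fs$report),
                     individuals = unclass(fi$report)), out("qc_report.json"))
    manifest$counts$qc <- list(sites_kept = ncol(geno),
                               individuals_kept = nrow(geno))
  }

  # --- kinship -------------------------------------------------------------
  if (config$stages$kinship) {
    K <- king_kinship(geno)
    pr <- prune_first_degree(K, threshold = config$kinship_threshold,
                             missingness = rowMeans(is.na(geno)))
    geno <- geno[pr$kept, , drop = FALSE]
    res$kinship <- K
    res$pruned <- pr
    manifest$counts$kinship <- list(removed = length(pr$removed),
                                    kept = length(pr$kept))
    .write_json(list(threshold = config$kinship_threshold,
                     removed = pr$removed), out("kinship_pruning.json"))
  }

  # --- panel ---------------------------------------------------------------
  if (config$stages$panel) {
    sites_now <- cohort$sites[match(colnames(geno), cohort$sites$id), ]
    pn <- design_panel(sites_now, geno, maf_min = config$maf_min,
                       hwe_alpha = config$hwe_alpha, thin_bp = config$thin_bp)
    geno <- geno[, pn$kept, drop = FALSE]
    res$panel <- pn$report
    .write_json(unclass(pn$report), out("panel_report.json"))
    manifest$counts$panel <- list(sites_kept = ncol(geno))
  }

  pop_map <- cohort$pop_map[rownames(geno)]
  group_map <- cohort$group_map[rownames(geno)]

  # --- sfs -----------------------------------------------------------------
  if (config$stages$sfs) {
    clusters <- intersect(.POPS5, unique(pop_map))
    # complete-case 5D SFS on a fixed per-cluster subsample keeps the joint
    # array small enough for direct composite-likelihood fitting
    nd <- config$fit_diploids_per_cluster
    sub <- unlist(lapply(clusters, function(cl)
      head(names(pop_map)[pop_map == cl], nd)))
    sfs5 <- joint_sfs(geno[sub, , drop = FALSE], pop_map, clusters,
                      folded = FALSE)
    res$sfs <- sfs5
    write_sfs(sfs5, out("joint_sfs.json"), "json")
    write_sfs(sfs5, out("joint_sfs.obs"), "fsc")
    write_sfs_marginals(sfs5, out("sfs_marginals.tsv"))
    manifest$counts$sfs <- list(polymorphic = sum(polymorphic_mask(sfs5) * sfs5$counts),
                                dropped_missing = attr(sfs5, "n_dropped_missing"))
  }

  # --- fit + compare -------------------------------------------------------
  if (config$stages$fit && config$stages$sfs) {
    fixed_all <- default_params("model4_SE_NC_admix")
    fits <- lapply(config$fit_models, function(mn) {
      sp <- param_space(mn)
      fixed <- fixed_all[intersect(names(fixed_all), sp$param)]
      fixed <- fixed[setdiff(names(fixed), c("T_SWC", "a_SE", "a_NC"))]
      fit_model_ecm(mn, res$sfs, space = sp, n_sims = config$fit_n_sims,
                    cycles = config$fit_cycles,
                    seed = .derive_seed(config$seed, 5), fixed = fixed)
    })
    res$fits <- fits
    res$ranking <- compare_models(fits)
    .write_json(lapply(fits, function(f)
      list(model = f$model, lnCL = f$lnCL, k = f$k, AIC = f$AIC,
           params = as.list(f$params), trace = f$trace, seed = f$seed)),
      out("fits.json"))
    .write_json(res$ranking, out("model_ranking.json"))
    manifest$counts$fit <- list(models = length(fits),
                                best = res$ranking$model[1])
  }

  # --- stats ---------------------------------------------------------------
  if (config$stages$stats) {
    ho <- observed_heterozygosity(geno)
    ho_by_cluster <- tapply(ho, pop_map[names(ho)], mean)
    fst_cluster <- pairwise_fst(geno, pop_map)
    big_groups <- names(which(table(group_map) >= 2))
    fst_group <- pairwise_fst(geno[group_map %in% big_groups, , drop = FALSE],
                              group_map, sort(big_groups))
    gen_d <- linearize_fst(fst_group)
    groups_here <- default_group_design(config$total_individuals)
    coords <- .group_coords(groups_here, config$seed)
    coords <- coords[coords$label %in% big_groups, ]
    geo_d <- geographic_distances(coords)
    mt <- mantel_test(gen_d[coords$label, coords$label], geo_d, n_perm = 999,
                      seed = .derive_seed(config$seed, 9))
    res$stats <- list(ho = ho, ho_by_cluster = ho_by_cluster,
                      fst_cluster = fst_cluster, fst_group = fst_group,
                      mantel = mt)
    write_distance_matrix(fst_cluster, out("fst_clusters.tsv"))
    write_distance_matrix(gen_d, out("genetic_distance_groups.tsv"))
    write_distance_matrix(geo_d, out("geographic_distance_km.tsv"))
    .write_json(list(ho_mean = mean(ho),
                     ho_by_cluster = as.list(ho_by_cluster),
                     fst_cluster_range = range(fst_cluster[upper.tri(fst_cluster)]),
                     mantel = mt), out("stats.json"))
    manifest$counts$stats <- list(individuals = length(ho),
                                  mantel_p = mt$p)
  }

  .write_json(manifest, out("manifest.json"))
  res$manifest <- manifest
  invisible(res)
}
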
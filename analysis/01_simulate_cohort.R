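#!/usr/bin/env Rscript
# Simulate the synthetic study cohort: 20 sampling groups in the five genetic
# clusters (SW, SE, C, NC, N) under the best-fit stepping-stone-with-admixture
# demography, with planted low-quality individuals and first-degree relatives
# so the QC stages downstream have ground truth. Writes the cohort as VCF +
# popmap under results/cohort/.

library(rhinopop)

seed <- 20251001
out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

demog <- build_named_model("model4_SE_NC_admix")
groups <- default_group_design(330)   # 20 groups; SE a single isolated group
cohort <- simulate_genotype_matrix(
  demog, groups, n_sites = 8000, missing_rate = 0.02,
  relative_pairs = 12, low_quality = 60, seed = seed)

write_vcf(cohort$geno, cohort$sites, file.path(out, "cohort.vcf"))
write.table(data.frame(id = cohort$individuals$id,
                       group = cohort$individuals$group,
                       cluster = cohort$individuals$cluster),
            file.path(out, "popmap.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cohort$individuals, file.path(out, "individuals.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cohort$relatives, file.path(out, "planted_relatives.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("cohort:", nrow(cohort$geno), "individuals x", ncol(cohort$geno),
    "sites;", sum(cohort$individuals$true_low_quality), "planted low-quality;",
    nrow(cohort$relatives), "planted parent-offspring pairs\n")
cat("wrote", file.path(out, "cohort.vcf"), "\n")
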
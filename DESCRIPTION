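Package: rhinopop
Title: Demographic Inference and Population Genomics for Fragmented Snub-Nosed Monkey Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for SNP-panel population genomics of the
    black-and-white snub-nosed monkey (Rhinopithecus bieti) and similarly
    fragmented five-population systems: coalescent simulation of competing
    origin and dispersal models (splits, admixture pulses, migration),
    site-frequency-spectrum composite likelihood with conditional-maximization
    fitting and AIC model selection, neutral SNP panel design (MAF, exact
    Hardy-Weinberg, 10-kb thinning, gene/CpG masks), hard-filter QC,
    KING-robust kinship pruning, Weir-Cockerham F_ST, observed heterozygosity,
    and Mantel isolation-by-distance testing. A synthetic-data module emulates
    the study design (20 sampling groups in 5 genetic clusters, planted
    relatives and low-quality individuals) so every stage is exercisable
    without the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    geosphere,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    rtracklayer
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
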
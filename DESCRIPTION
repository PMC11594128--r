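Package: crossblup
Title: Multi-Breed Genomic Prediction Simulation with LD Phase Consistency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation pipeline for studying genomic selection across small
    cattle populations. Generates multi-breed phased haplotype panels with a
    forward-in-time founder/drift model, expands them to large populations by
    haplotype-block resampling so that breed-specific linkage disequilibrium
    (LD) and allele frequencies are preserved, simulates quantitative traits
    under contrasting QTL architectures, fits GBLUP via the mixed-model
    equations with a VanRaden genomic relationship matrix, and quantifies how
    cross-population prediction accuracy tracks the persistence of LD phase
    between breeds. Includes distance-binned signed-r LD profiles, the cor100
    phase-consistency statistic, common-LD SNP-set marker selection,
    reference/validation scenario builders, replicated cross-validation, and
    PLINK/VCF import and export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
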
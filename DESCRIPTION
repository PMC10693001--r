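Package: migrasv
Title: Structural-Variant Population Genomics of Migratory Songbirds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for studying structural variants (SVs)
    in wild populations of migratory birds. Provides multi-caller SV consensus
    genotyping and cohort merging with SURVIVOR-style breakpoint clustering,
    genome-landscape summaries (window densities, GC content, size spectra,
    repeat overlap), population-genetic statistics (folded allele-frequency
    spectra, Tajima's D, Hudson's FST, the population branch statistic,
    inversion linkage disequilibrium with size-matched colinear controls, PCA),
    migratory-trait extraction from geolocator tracks (rhumb-line direction and
    distance, great-circle route-fraction timing), and a Bayesian sparse linear
    mixed model GWAS with polygenic-score cross-validation. A synthetic-data
    module generates cohorts with known truth (Balding-Nichols population
    structure, noisy caller emulation, genotype-driven phenotypes and
    constant-speed migration tracks) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0)
LinkingTo: Rcpp
Config/testthat/edition: 3
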
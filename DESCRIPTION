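Package: blocnet
Title: Allele-Specific SNP Correlation Networks and Multi-SNP Bloc Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds allele-specific correlation networks from case/control
    genotype data and tests multi-SNP allele patterns ("blocs") for disease
    association. Every SNP pair is scored with a four-facet custom correlation
    coefficient (CCC) computed from fast allele co-occurrence tallies, one value
    per allele combination, so that correlations confined to a subgroup of
    individuals are not diluted by genetic heterogeneity. The top correlations
    become edges of a network with two nodes per SNP; connected components
    (blocs) are extracted and each entire allele pattern is tested with odds
    ratios, G-tests of independence, Bonferroni correction, and permutation
    based family-wise error control. Includes readers and writers for PLINK
    PED/MAP, VCF and a plain dosage-matrix format, a synthetic genotype
    simulator with embedded multi-SNP patterns and subgroup heterogeneity,
    validation procedures (phenotype-label permutation, genotype shuffling,
    bootstrap subsampling, network density sweeps), and plotting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
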
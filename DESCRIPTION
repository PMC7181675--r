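Package: rohscan
Title: Runs of Homozygosity, Selection Scans and Inbreeding for SNP-Array Genotypes
Version: 0.1.0
Authors@R: person("rohscan", "maintainers", email = "rohscan@example.org", role = c("aut", "cre"))
Description: Tools for population-genomic analysis of dense diploid SNP-array
    genotypes, motivated by the study of closed livestock populations such as
    Island versus mainland Jersey cattle. Reads and writes PLINK-style binary
    genotype filesets; applies call-rate, minor-allele-frequency and
    identity-by-descent quality control; prunes markers by linkage
    disequilibrium; detects runs of homozygosity (ROH) under per-run
    heterozygote, missingness and gap constraints; clusters ROH across
    individuals and tests cluster membership for association between groups;
    computes per-marker and multilocus Weir-Cockerham fixation indices with a
    sigma-threshold caller for candidate selection regions; and estimates
    inbreeding (F_ROH, F_IS), pairwise relatedness (method-of-moments IBD) and
    population structure (Hardy-Weinberg-normalized PCA). A seeded
    Balding-Nichols genotype simulator with planted autozygous tracts provides
    ground truth for every stage, and a single-config pipeline orchestrates
    the full analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
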
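Package: grmpart
Title: MAF- and LD-Stratified Partitioning of Deregressed-Proof Variance
    with Genomic and Pedigree Relationship Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for partitioning the variance of deregressed proofs
    (DRP) across minor-allele-frequency (MAF) and linkage-disequilibrium
    (LD) classes of genome-wide variants, in the style of GREML-MS and
    GREML-LDMS analyses of livestock populations.  Includes readers and
    writers for VCF and PLINK-style genotype files, the usual array
    quality-control filters (call rate, Hardy-Weinberg, MAF), windowed LD
    scores and segment-based LD stratification, genomic relationship
    matrices (VanRaden methods 1 and 2 and the alpha-scaled family),
    pedigree numerator relationship matrices, a multi-component
    average-information REML engine with EM fallback, expected variance
    partitions under alternative GRM scalings, and a synthetic-data module
    that simulates cattle-like genotypes, pedigrees and DRP phenotypes
    with known per-class genetic variances so that every stage of the
    pipeline can be validated against simulated truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
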
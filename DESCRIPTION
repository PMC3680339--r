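Package: rfgwas
Title: Random-Forest Genome-Wide Association on Deregressed Breeding Values
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for random-forest based genome-wide
    association analysis of quantitative traits in pedigreed livestock
    populations, modelled on the analysis of ultrasound backfat thickness in
    Canchim beef cattle. Covers pedigree relationship matrices and
    animal-model BLUP with known variance ratio, deregression of estimated
    breeding values into pseudo-phenotypes with information weights, genotype
    quality control and naive median imputation, two-step random-forest
    variable-importance SNP selection with kinship-minimizing subsampling,
    forward stepwise regression with sequential partial R-squared
    decomposition and a permutation bias test, and linkage-disequilibrium
    windows with gene/QTL interval annotation. Includes a gene-dropping
    simulator of pedigrees, LD-structured genotypes and phenotypes with
    planted QTL so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    ranger,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    randomForest,
    rtracklayer,
    vcfR,
    optparse,
    yaml
Config/testthat/edition: 3
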
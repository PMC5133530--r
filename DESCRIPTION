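Package: pedscan
Title: Variance-Component QTL Mapping and Score-Test GWAS in Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood fitting of multivariate variance-component
    trait models on pedigrees (additive polygenic, dominance, household and
    environmental components; theoretical or SNP-based kinship), a fast
    per-SNP score test with likelihood-ratio refinement of top hits, the
    surrounding quality control (call rates, minor allele frequency,
    Hardy-Weinberg exact test in founders), genomic-control and
    multiple-testing machinery, and a pedigree/genotype/trait simulator so
    the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
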
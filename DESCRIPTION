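Package: tetraGS
Title: Genomic Selection for Autotetraploid Breeding Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic prediction in autotetraploid, dioecious
    breeding programmes built on factorial crossing designs. Provides
    tetraploid allele-dosage handling (0-4 coding), a VanRaden-type
    realised genomic relationship matrix generalised to ploidy m,
    single-kernel REML/GBLUP with Henderson prediction-error-variance
    accuracies, sequential Wald tests for fixed-effect structures,
    leave-one-out cross-validated predictive ability with sub-population
    and training-set-size analyses, dosage PCA and trait descriptive
    statistics, and a polysomic-inheritance simulator (binomial founder
    dosages with Balding-Nichols species differentiation, hypergeometric
    bivalent gametes with optional double reduction, multi-year additive
    phenotypes on females) together with a gene-dropping Monte-Carlo
    oracle for validating relationship matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
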
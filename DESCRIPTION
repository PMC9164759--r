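Package: metags
Title: Meta-Analysis of Genomic Prediction from Population-Level Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Combines single-population SNP-BLUP genomic evaluations into a
    multi-population analysis using only shared summary statistics: per-SNP
    effect estimates or right-hand sides, precision (Z'R-1Z) matrices, allele
    frequencies, and variance components. The meta mixed-model equations
    reproduce the raw-data multi-trait BLUP solutions without access to
    individual genotypes or phenotypes. Includes trait-wise rescaling of the
    shared precision matrix, block-wise LD-based imputation of summary
    statistics for SNPs missing in some populations, a raw-data joint BLUP
    oracle for verification, and a synthetic two-population sire-model data
    generator with block-LD genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
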
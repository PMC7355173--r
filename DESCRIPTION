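Package: gxepool
Title: Gene-Based Gene-Environment Interaction Analysis with LD-Adjusted
    Brown Pooling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits per-SNP linear gene-environment (GxE) interaction models
    and pools the SNP-level interaction p-values to gene-level p-values with
    Brown's method, using a linkage-disequilibrium-derived covariance of the
    log p-values (Kost-McDermott cubic approximation). Includes SNP quality
    control (call rate, minor allele frequency, Hardy-Weinberg equilibrium),
    permutation-based validation, genomic-control inflation estimation, a
    dichotomized-exposure sensitivity analysis, readers and writers for
    PLINK .raw dosage tables, PLINK .ld square matrices, TSV phenotype and
    gene-map tables and minimal VCF, and a seeded synthetic-cohort generator
    with block-LD genotypes in Hardy-Weinberg equilibrium and bounded skewed
    exposures for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, yaml, vcfR
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
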
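Package: pleiogene
Title: Gene-Level Pleiotropy Mapping Across Disorders from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for detecting gene-level pleiotropy across
    multiple disorders from GWAS summary statistics. Aggregates SNP-level
    association statistics into gene-level p-values using a weighted
    sum-of-chi-squares test under local linkage disequilibrium, converts them
    to signed Z-statistics, and tests the composite null hypothesis of
    non-pleiotropy with a product-normal intersection-union test on
    de-correlated Z-statistics, alongside direct-FDR and maximum-P comparator
    methods and a likelihood-ratio test for overall pleiotropy. Also provides
    LD score regression for heritability and cross-trait genetic correlation
    with block-jackknife uncertainty, hierarchical clustering of the trait
    correlation matrix, a bidirectional two-sample Mendelian randomization
    screen (inverse-variance weighted, weighted median, MR-Egger), and a
    synthetic summary-statistics generator with block LD structure for
    validation and power studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
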
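Package: varwarehouse
Title: Star-Schema Warehousing and Query Benchmarking for Genomic Variant Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale benchmarking suite for genomic variant data
    warehouses. Simulates population-structured exome cohorts from
    Hardy-Weinberg genotype probabilities with per-ethnicity allele
    frequencies, materializes a star schema of genotype calls at several
    physical storage levels (raw facts, pre-aggregated counts, denormalized
    wide tables, and a materialized-aggregate cube), ships twelve
    parameterized biomedical SQL queries with independent in-memory
    reference oracles, and automates timed benchmark runs over columnar
    (Parquet) storage through an embedded SQL engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    arrow,
    DBI,
    RSQLite,
    dplyr,
    ggplot2,
    jsonlite,
    stats,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
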
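Package: vardb
Title: Variant Warehouse with Genotype-Aware Queries and Family-Based Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Loads VCF variant calls, PED pedigrees, transcript-consequence
    annotations (snpEff or VEP), and user-supplied interval annotation tracks
    into a single-file SQLite database with per-variant compressed genotype
    arrays. Provides a SQL query interface extended with a per-sample
    genotype-filter expression language (COLUMN.SAMPLE notation), built-in
    screens for Mendelian inheritance patterns (de novo, autosomal recessive,
    autosomal dominant, compound heterozygotes), per-site population-genetics
    statistics (Hardy-Weinberg equilibrium, inbreeding coefficient,
    nucleotide diversity), pathway and protein-interaction tools, and a
    synthetic-fixture generator with ground-truth labels for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    IRanges,
    S4Vectors,
    igraph,
    rtracklayer,
    parallel,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
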
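Package: bsascan
Title: Two-Locus BSA-Seq Mapping: SNP-Index Scans, Segregation Tests and
    Recombinant Fine-Mapping
Version: 0.1.0
Authors@R:
    person("BSA", "Scan Developers", email = "bsascan@example.org",
           role = c("aut", "cre"))
Description: Bulked-segregant analysis by sequencing (BSA-seq) for traits
    controlled by two recessive loci with duplicate-dominant epistasis
    (15:1 F2 segregation). Provides a seeded F2 cross simulator (Haldane
    recombination, phenotype bulks, Poisson/binomial read depths, VCF
    output), site filtering of a four-sample variant table, parent-polarized
    SNP-index and delta(SNP-index) computation with per-site Fisher exact
    tests, sliding-window genome scans with candidate-region calling,
    chi-square goodness-of-fit tests for Mendelian segregation ratios
    (including the 7:4:4:1 two-gene F2:3 class test), and recombinant
    breakpoint intersection for marker-based fine mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    data.table,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
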
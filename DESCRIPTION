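Package: rohmap
Title: Homozygosity Mapping and Recessive Variant Filtering for Inbred Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps autosomal recessive Mendelian traits in inbred populations
    by runs-of-homozygosity (ROH) analysis of SNP-array genotypes. Implements
    sliding-window ROH detection with PLINK 1.9 semantics, population-dependent
    parameter calibration (a false-positive-controlled minimum marker count and
    a density/gap grid search on a simulated fully homozygous individual),
    pooling and allelic matching of ROH across cases and controls,
    Hardy-Weinberg exact-test genotype QC, inheritance-model filtering of
    SNVs/indels and private-variant filtering of SVs/MEIs from multi-sample
    VCFs, consequence classification against a gene model, and segregation and
    allele/carrier frequency arithmetic. A synthetic-cohort generator with a
    planted autozygous segment and causal variant makes the full pipeline
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
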
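Package: xomap
Title: Haplotype Maps and Fine-Scale Crossover Localization in
    Pseudo-Testcross Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs parental haplotypes from low-coverage
    whole-genome genotypes of F1 pseudo-testcross populations and maps
    meiotic crossovers at fine scale.  Implements an SNV filtering
    cascade (repeat masking, segregation distortion, sampled-r2 linkage
    disequilibrium, depth-aware missingness), sliding-window LD phasing,
    a binomial/Bayes haplotype window caller with an empirically
    estimated genotyping error rate, skeleton-bin construction,
    logistic-regression crossover interval localization, Marey-map
    recombination rate interpolation, and a suite of interval enrichment
    statistics (Monte-Carlo shuffle tests, matched cold-region sampling,
    transposon-family Fisher tests, aggregate profiles, binned rank
    correlations, Poisson goodness-of-fit, and crossover-count GLMs).
    A bundled meiosis and sequencing simulator generates populations
    with known crossover truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    vcfR,
    zoo,
    yaml,
    methods,
    stats,
    utils,
    tools
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    Biostrings,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
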
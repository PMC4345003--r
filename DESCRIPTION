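Package: epiqtl
Title: Two-Stage Epistatic eQTL Discovery with Rank-Transform Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovery of pairwise epistatic expression quantitative trait
    loci (eQTLs) from genotype and expression matrices using two restricted
    search spaces (cis-trans and cis-cis). Provides genotype quality control
    (minor allele frequency, missingness, Hardy-Weinberg equilibrium),
    population stratification by genotype PCA with Tracy-Widom component
    significance and iterative outlier removal, rank-transform regression
    for marginal and product-coded interaction effects with
    Benjamini-Hochberg and Bonferroni multiple-testing control, EM-based
    linkage-disequilibrium filtering of candidate SNP pairs, post-hoc
    redundancy grouping and stepwise-AIC independence analysis, and
    enrichment of interacting SNP pairs in Hi-C contact pairs and
    promoter/enhancer annotation tracks. A seeded synthetic-data generator
    produces genotype, expression and annotation fixtures with configurable
    linkage disequilibrium, population structure, missingness and planted
    interaction effects.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    yaml,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
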
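Package: triocnv
Title: Trio-Based Detection and Inheritance Analysis of Recurrent
    Neurodevelopmental-Disorder CNVs from SNP-Array Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of recurrent copy number variants
    (CNVs) at 13 genomic regions associated with neurodevelopmental
    disorders (NDDs), in mother-father-child trio cohorts genotyped on
    SNP arrays. Provides a trio cohort simulator with known ground truth
    (marker maps, Mendelian genotypes, implanted deletions and
    duplications, mosaic gains, Log R Ratio / B Allele Frequency signal
    rendering), a six-state hidden Markov model CNV caller with fragment
    merging and breakpoint refinement, sample- and trio-level signal
    quality control, parental-frequency / blacklist / size filters and
    NDD-region matching, inheritance and parent-of-origin classification
    from trio genotype evidence, mosaic-fraction estimation from BAF
    bands, and prevalence statistics (Wilson score intervals, two
    proportions Z-tests, transmission disequilibrium tests) with
    publication-style summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
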
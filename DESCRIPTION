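Package: karyoDosage
Title: Read-Depth Karyotyping of Segmental Allotetraploid Rice
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Whole-genome read-depth karyotyping for a synthetic segmental
    allotetraploid rice population. Implements per-chromosome normalized
    coverage (the Key-value statistic), simulation-derived gain/loss
    thresholds, whole-chromosome and arm-level aneuploidy calling from
    10-kb binned counts, a karyotype-string grammar with
    simple/compound/hidden/segmental classification, population-level
    statistics (exact binomial gain-vs-loss tests, exact Poisson tests,
    Poisson-permutation aneuploidy-propensity classification, reciprocal
    cross bias, factor correlations), euploid-vs-aneuploid trait
    comparison with a karyotype-specific association screen, and a
    seeded count-level coverage simulator used to calibrate and test the
    caller.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: CopyNumberVariation, Coverage, Sequencing, Genetics
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'caller.R'
    'genome.R'
    'io.R'
    'karyotype.R'
    'phenostats.R'
    'pipeline.R'
    'popstats.R'
    'simulate.R'
    'thresholds.R'
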
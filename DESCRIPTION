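Package: tetradqtl
Title: QTL Mapping of Binary Ploidy Phenotypes in Tetrad-Structured Yeast Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping binary traits (such as spontaneous whole-genome
    duplication, or autodiploidization) in haploid F1 segregants from a cross of
    two yeast strains. Provides a tetrad-aware cross simulator with a single-locus
    penetrance model and sparse sequencing-count emission, two-state hidden Markov
    model genotype inference from per-marker parental allele read counts,
    pre-mapping quality control (segregation distortion, genotype similarity,
    crossover-count outliers), single-QTL genome scans for binary phenotypes by
    EM interval mapping and Haley-Knott regression with genome-wide permutation
    thresholds, forward/backward stepwise multi-QTL model selection with held-out
    model fitting and allele-effect estimation, and bulk-segregant enrichment
    analysis of phenotype-sorted sequencing pools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
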
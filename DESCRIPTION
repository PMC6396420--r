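Package: nipgeno
Title: Bayesian Noninvasive Prenatal Genotyping from Cell-Free DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers fetal genotypes at biallelic parental variant sites from
    maternal-plasma cell-free DNA. Implements a per-fragment Bayesian mixture
    model in which each cfDNA fragment is weighted by a fragment-length-dependent
    fetal fraction, with Mendelian trio priors and per-site posterior genotype
    probabilities. Includes estimation of total and per-length fetal fractions
    from fetal-informative sites, evidence extraction from alignments, a
    fetal-fraction and depth subsampling simulator, a fully synthetic cfDNA
    trio generator with known truth, and a random-forest recalibration stage
    for post-hoc variant score filtering. Results are returned as tibbles and
    written as standard VCF.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    patchwork,
    pROC,
    purrr,
    ranger,
    readr,
    rlang,
    Rsamtools,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
Config/testthat/edition: 3
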
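Package: raregerm
Title: Rare Germline Variant Prioritization, Burden and Survival Analysis
    for B-Cell Neoplasm Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for the analysis of rare, putatively
    dysfunctional germline variants in cancer cohorts, motivated by B-cell
    lymphoid neoplasms. Merges per-sample call sets from multiple variant
    callers into a consensus with genotype-quality, depth and allele-fraction
    filters; normalizes indel representation for cross-caller matching;
    prioritizes variants by population rarity (popmax), protein-truncating
    consequence and CADD-style deleteriousness within a curated cancer gene
    panel; detects homozygous, compound-heterozygous and germline-somatic
    second-hit events including loss of heterozygosity, and flags likely
    clonal-hematopoiesis mosaics by tumor-compartment allele fraction;
    performs gene-level dominant collapsing burden tests against public
    control allele counts with Benjamini-Hochberg correction and genomic
    inflation diagnostics; and screens gene carrier status against
    time-to-first-treatment and overall survival with covariate-adjusted Cox
    models. A synthetic cohort generator with known ground truth supports
    calibration, power and parameter-recovery studies without access to
    controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    vcfR,
    survival,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
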
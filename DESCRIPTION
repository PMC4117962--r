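Package: recmapr
Title: Mapping Recessive Defects from SNP Arrays, Sequence Variants and
    Survival Records
Version: 0.1.0
Authors@R:
    person("recmapr", "maintainers", email = "recmapr@example.org",
           role = c("aut", "cre"))
Description: A pipeline for mapping lethal recessive defects in livestock
    populations from SNP-array genotypes, whole-genome sequence variants and
    calf survival records. Provides a synthetic-cohort simulator that plants
    a founder haplotype carrying a nonsense allele, SNP-array quality
    control, a VanRaden genomic relationship matrix, an exact linear
    mixed-model association scan, run-of-homozygosity detection and
    case-segment intersection, haplotype carrier statistics with a
    Hardy-Weinberg exact test, recessive-compatibility variant filtering
    with stop-gain consequence annotation, and Kaplan-Meier survival
    contrasts of carrier matings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
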
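Package: miraging
Title: MicroRNA Target Anticorrelation, Small RNA Annotation, and Sponge
    Design for Brain-Aging Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying age-regulated microRNAs in bulk
    transcriptome data, built around the miR-29/brain-aging analysis
    workflow: mismatch-tolerant small RNA-seq preprocessing and two-phase
    read annotation against mature miRNA references, canonical seed-site
    scanning on 3'-UTRs with site mutagenesis and bulged sponge (decoy)
    construct design, a bootstrap-null Kolmogorov-Smirnov test for target
    anticorrelation with miRNA expression, triple-test (binomial, Fisher,
    hypergeometric) Hochberg-consensus target overrepresentation, and
    direction-concordance typing of intersected differential-expression
    tables. Includes a seeded synthetic-data generator emulating the
    age-series design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
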
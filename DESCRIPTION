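Package: mitotriage
Title: Two-Step Genetic Diagnosis Pipeline for Suspected Mitochondrial
    Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a two-stage next-generation-sequencing diagnostic
    strategy for patients with a probable or possible mitochondrial
    disease: mitochondrial DNA analysis (heteroplasmy-aware point-variant
    calling from pileups, split-read detection of large deletions with
    exact breakpoints, qPCR-based copy-number depletion calling) followed
    by inheritance-model filtering of whole-exome variant tables
    (autosomal-recessive homozygous, compound-heterozygous, X-linked, and
    panel-restricted dominant models), supported by runs-of-homozygosity
    mapping and mitochondrial disease criteria scoring.  A synthetic
    cohort generator recreates a 117-family study cohort from a packaged
    planted-truth manifest so that cohort-level diagnostic-yield tables
    are reproducible end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
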
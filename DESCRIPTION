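Package: xenomir
Title: Detection and Contamination Diagnostics for Plant miRNAs in Animal Small-RNA Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies small-RNA sequencing reads by exact full-length identity
    against a kingdom-annotated mature-miRNA catalog, applies a >=20-nt
    host-genome exclusion filter, computes per-library abundance statistics for
    detected plant (xeno-) miRNA families, attributes miR168-style sequence
    variants to monocot or dicot origin, and diagnoses whether plant miRNAs in
    animal libraries reflect dietary uptake or cross-contamination within a
    multiplexed sequencing run (marker-sequence tracing, profile similarity,
    bleed-rate estimation). Includes a deterministic simulator of multiplexed
    runs with known ground truth for end-to-end validation.
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
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
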
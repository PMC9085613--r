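Package: uvshift
Title: Sex-Biased Expression and Convergent Expression Evolution in
    Transitions from Dioicy to Monoicy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative-transcriptomics toolkit for haploid (UV) sexual
    systems: calls sex-biased genes from TPM matrices, assembles
    single-copy ortholog sets across dioicous-monoicous species pairs,
    computes the delta-X directional-selection statistic for expression
    shifts, reconstructs ancestral sex-bias states under an Mk model with
    branch gain/loss mapping, tests expression-profile similarity with
    dependent- and independent-correlation comparisons, detects convergent
    monoicous expression changes with a permutation null, and measures
    pairwise coding-sequence divergence (Nei-Gojobori dN/dS).  Ships a
    seeded synthetic-data generator with planted ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    limma,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    yaml,
    optparse
Config/testthat/edition: 3
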
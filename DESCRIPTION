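Package: ampliquant
Title: Quantification of CRISPR Genome-Editing Outcomes from Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, scriptable pipeline for quantifying genome-editing
    outcomes (indels and base edits) from raw amplicon or targeted
    whole-genome sequencing reads. Provides native quality trimming and
    filtering, paired-end overlap merging, semi-global affine-gap alignment of
    reads to one or more reference amplicons or alleles, indel left-alignment
    and signature counting, modified/unmodified read classification,
    per-position indel and substitution profiles, reference-anchored alignment
    views of the most frequent editing outcomes, and a seeded read simulator
    with truth labels so every stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    ggplot2,
    rlang,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
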
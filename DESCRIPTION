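Package: polymads
Title: Gene-Family Phylogenomics for Allopolyploid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide analysis of a
    transcription-factor gene family (modelled on the MADS-box family) in
    allopolyploid genomes such as hexaploid bread wheat. Identifies family
    members by profile scans of the MADS (PF00319) and K-box (PF01486)
    domains, classifies genes into M-type and MIKC-type superclades and
    subfamilies with bootstrapped neighbor-joining trees, detects homeologous
    triads and scores their subgenome balance, calls tandem and segmental
    duplications from coding-sequence identity, estimates Ka/Ks by the
    Nei-Gojobori (1986) pathway method with Jukes-Cantor correction and dates
    duplication events, and clusters stress-expression profiles with K-means.
    Includes a synthetic allohexaploid genome generator with full ground
    truth for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
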
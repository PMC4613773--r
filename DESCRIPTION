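Package: bactile
Title: BAC Tiling Paths, Dotplot Structural Comparison and MHC Class I
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building physical maps from large-insert (BAC) clone
    sequences: exact word-match anchoring and chaining to detect oriented
    pairwise overlaps, orientation resolution and tiling-path construction
    with gap calling, Gepard-style dotplot comparison against a reference
    chromosome with structural-event calling (indels, inversions,
    interspersed repeats, N-run artefacts and displaced-prefix
    misassemblies), and motif/domain-based classification of MHC class I
    proteins as classical (Ia) or nonclassical (Ib).  Includes seeded
    synthetic-data generators (chromosomes, clone sets, class I proteins
    with planted ground truth) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    rtracklayer,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
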
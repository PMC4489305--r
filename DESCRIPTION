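Package: mirharmony
Title: Sequence-Keyed Harmonization of miRNA Nomenclature Across
    miRBase Versions and Profiling Platforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes microRNA (miRNA) nomenclature across miRBase release
    versions and commercial profiling-platform annotations by keying identity
    on the normalized mature sequence rather than on names. Provides
    translation of miRNA name lists between any two namespaces (a
    species-scoped miRBase release or a platform probe set), overlap of two
    namespaces, sequence-keyed update and intersection of expression matrices
    with value carryover, reconstruction of per-accession name histories
    across an ordered release series with stringent and relaxed queries, and
    curation of platform annotations for name-to-sequence consistency. A
    deterministic synthetic fixture generator emits miniature release series
    with scripted renames, deletions, additions and sequence collisions,
    derived platforms with injected defects, and expression matrices, so the
    whole pipeline is testable offline. Includes readers and writers for a
    canonical release TSV, the mature FASTA dialect, platform CSV and matrix
    CSV/TSV, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
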
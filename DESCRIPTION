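Package: dnawalkr
Title: Non-Degenerate 2D Walk Visualization of DNA Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms DNA sequences into two-dimensional walks using five
    invertible (non-degenerate) graphical methods (Gates, Yau, Squiggle,
    Randic nucleotide tablature, and Qi dinucleotide tablature), persists the
    walks in compressed columnar Parquet storage with inclusive x-range
    querying, extrema-preserving (min-max) downsampling to a fixed point
    budget, and time-based cache expiry, and renders publication-ready overlay
    plots. Every transform has an exact inverse, so a decoded walk reproduces
    the originating sequence - a built-in correctness oracle. Includes a
    FASTA reader with batch capacity validation, a seeded synthetic sequence
    generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    arrow,
    dplyr,
    ggplot2,
    jsonlite,
    parallel,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
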
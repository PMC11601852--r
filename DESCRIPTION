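Package: bimove
Title: Bidirectional Move-Structure Index for Run-Length Compressed
    Approximate Pattern Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a run-length compressed full-text index over DNA
    sequence collections based on the move structure: run-indexed tables
    that evaluate the Burrows-Wheeler LF mapping and the phi/inverse-phi
    suffix-array permutations by cache-friendly table jumps.  Forward and
    reverse LF tables are kept synchronized so that a pattern can be
    extended by characters on either end in arbitrary order, which enables
    lossless approximate pattern matching with search schemes: every
    occurrence of a read within a chosen Hamming or edit distance is
    reported.  Locating uses a toehold suffix-array sample maintained
    across extensions together with phi move tables and a sparse permuted
    LCP array.  Includes bit-packed table encodings, index serialization,
    SAM output, and deterministic synthetic pan-genome generators for
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
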
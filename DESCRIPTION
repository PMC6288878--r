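Package: edlogo
Title: Enrichment-Depletion Sequence Logos with Stabilized Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequence logo plots that highlight both enrichment and
    depletion of symbols at each position of a motif or other positional
    profile. Heights are median-centered log2 ratios of foreground to
    background probabilities, so the most parsimonious description of a
    position (fewest, smallest glyphs) is drawn; symbols may be arbitrary
    strings and each position may use its own alphabet. Includes standard
    information-content and weighted Kullback-Leibler logos for comparison,
    pseudocount and Empirical Bayes stabilization of log-ratio estimates
    from count data, readers for delimited count/probability tables, JASPAR
    position frequency matrices and FASTA alignments, a deterministic SVG
    renderer, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
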
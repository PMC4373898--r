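Package: ccmscan
Title: Conformational Consensus Motif Screening of Cotransin-Sensitive
    Signal Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying proteins as cotransin-sensitive from
    label-swap SILAC expression ratios, scanning signal anchor sequences
    for the two-cavity conformational consensus motif with a fuzzy
    residue-class pattern engine, testing motif enrichment by Fisher's
    exact test, profiling signal-sequence hydrophobicity (GRAVY) and
    length distributions, projecting motif cavities onto ideal
    alpha-helix geometry, designing minimal point-mutation sets that
    introduce the motif into a resistant signal anchor, and fitting
    sigmoidal concentration-response (IC50) curves to
    biosynthesis-inhibition readouts. Includes synthetic-data generators
    for every input so the full pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
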
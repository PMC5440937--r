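Package: motifRing
Title: Circular Sequence Logos with Intra-Motif Dependency Ribbons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds circular sequence logos that display both the
    position-specific nucleotide composition of a DNA or RNA motif and the
    pairwise statistical dependencies between motif positions. From an
    aligned set of motif instances it computes per-position frequencies and
    WebLogo-style information content, measures intra-motif dependency for
    every position pair with a chi-square Q statistic or mutual information
    (with a Chebyshev significance bound against a permutation null),
    serializes motifs in a JSON-Graph exchange format, converts JASPAR and
    MEME count matrices, filters background-level links, and renders the
    result as a static SVG chord diagram. A synthetic-alignment generator
    with controlled conservation and injected pairwise dependencies supports
    fully reproducible analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
biocViews: MotifAnnotation, SequenceMatching, Visualization, Transcription
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
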
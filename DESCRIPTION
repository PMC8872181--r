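Package: mitorearr
Title: Comparative Mitogenome Composition and Gene-Order Rearrangement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated vertebrate
    mitochondrial genomes: GenBank flat-file input/output with circular
    coordinate handling, nucleotide composition and AT/GC strand-skew
    statistics, codon usage and relative synonymous codon usage (RSCU)
    under the vertebrate mitochondrial code, start/stop codon tabulation,
    intergenic spacer and overlap reports, and uncorrected p-distances.
    Gene orders are extracted, canonicalized, and classified against a
    registry of named arrangement types, and rearrangements between
    orders are modelled with an explicit tandem duplication/random loss
    (TDRL) event calculus that can validate hypothesised scenarios and
    search for minimal ones. A seeded synthetic mitogenome generator with
    ground-truth manifests makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
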
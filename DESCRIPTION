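Package: plastomeDiff
Title: Comparative Analysis of Near-Identical Chloroplast Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pairwise comparative analysis of complete chloroplast
    (plastid) genomes: detection of the quadripartite LSC/IRb/SSC/IRa
    architecture from sequence alone, canonical rotation of circular
    plastomes, microsatellite (SSR) scanning with class-specific repeat
    thresholds, anchor-based alignment of near-identical genome pairs with
    substitution, indel and micro-inversion calling and classification
    (transition/transversion spectrum, homopolymer slippage indels, hairpin
    stem arms), IR junction/gene distance analysis, and a synthetic
    plastome-pair generator that plants mutations with a fully known truth
    set for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
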
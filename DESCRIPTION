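Package: nociscreen
Title: Kinase Substrate Screening and Nociceptor Assay Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for identifying candidate substrates of the
    proline-directed kinase Cdk5 in nociceptor-enriched proteomes and for
    analysing the functional assays used to validate them. Includes consensus
    motif scanning with position-specific scoring, membrane-topology site
    filtering and decapeptide extraction; thresholded single-cell expression
    binarization, prevalence and conditional coexpression statistics with
    network export; ratiometric Fura-2 calcium trace processing with
    responder classification (mean plus three standard deviations of the
    non-responder peak distribution) and per-mouse summaries normalised to
    KCl; lickometer aversion metrics; and seeded synthetic-data generators
    for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
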
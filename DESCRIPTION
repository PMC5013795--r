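Package: viromimic
Title: Predicting Host Immune Proteins from Viral Mimicry in Viromes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for predicting candidate immune proteins of a host from
    virome sequence data via viral mimicry. Builds mock viromes by fragmenting
    viral genomes, searches host proteins against six-frame translations of
    virome fragments with a seed-and-extend local aligner using Karlin-Altschul
    E-value statistics, aggregates evidence per protein under a minimum-unique-
    fragment rule, triages candidates through reference-proteome homology and
    PSSM domain scanning into annotated, viral-like and novel classes, tests
    enrichment of pattern-recognition and apoptosis domains, and predicts
    transmembrane segments by hydropathy. Includes a mimicry simulator with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    jsonlite
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
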
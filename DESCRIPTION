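Package: lectinseq
Title: De Novo Glycan Sequencing from Lectin Binding Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting glycan structures from lectin array binding
    profiles. Parses glycans in CFG-style IUPAC-condensed notation as rooted
    labeled trees, enumerates connected subtree motifs with exact
    unspecified-substituent context, binarizes relative-fluorescence binding
    signals over a log-spaced threshold ladder, trains a fully visible
    Boltzmann (conditional logistic) model linking motifs to lectin features,
    generates a plausible candidate glycan space with an order-2 Markov
    growth model, and ranks candidates by model likelihood. Includes mutual
    information analysis of lectin-motif specificity, first- versus
    second-order cross-entropy model comparison, train/test evaluation
    harnesses with rank-group binomial enrichment, and a synthetic benchmark
    generator with planted lectin specificities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
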
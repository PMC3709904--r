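Package: tfpartner
Title: Functional Classification of Transcription Factor Binding Partners
    from Sequence Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts whether the binding partner of a known transcription
    factor (TF) is itself a TF, a transcription co-factor (TcoF), or another
    nuclear protein, using only the amino-acid composition of the two
    interacting sequences. Each protein is summarised by the average of
    AAindex1 physico-chemical indices over its residues; an interacting pair
    becomes the concatenation of the two per-protein vectors. Two
    order-symmetric Random Forest ensembles are trained, each composed of a
    forward- and a reverse-ordered sub-model whose confidence scores are
    averaged: Model 1 separates TF/TcoF partners from other nuclear
    proteins, Model 2 separates TcoFs from TFs, and a cascade of the two
    yields a three-class call. Includes an AAindex1 flat-file reader and
    writer, FASTA and interaction-pair table input, stratified k-fold
    cross-validation and split evaluation with accuracy, sensitivity and
    specificity, a synthetic-data generator with planted compositional
    class signal, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    ranger,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
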
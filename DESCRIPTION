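Package: oligostate
Title: Predicting the Number of Subunits of Homo-Oligomeric Proteins from Sequence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for curating homo-oligomer stoichiometry (number of
    subunits, NS) annotations from UniProt-style XML, embedding protein
    sequences through a pluggable encoder interface, and training and
    evaluating a bidirectional GRU + multi-head attention classifier that
    predicts NS from sequence alone. Includes macro-averaged multi-class
    metrics, train/test splitting and k-fold cross-validation, dataset
    characterization utilities (label distributions, EC-number stoichiometry
    diversity, pairwise global-alignment identity), and seeded synthetic-data
    generators so the full pipeline runs without network access.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    xml2,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
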
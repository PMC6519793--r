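Package: dgcminer
Title: Mining Disease-Gene-Chemical Relationships from Annotated Abstracts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Extracts disease-gene-chemical triplet relationships from
    entity-annotated biomedical abstracts. Reads PubTator-format corpora,
    builds candidate evidence sentence pairs (a gene-chemical relation
    sentence plus a disease context sentence), classifies them with a
    bidirectional LSTM over a mention-aligned parallel sentence-pair
    encoding (word embeddings concatenated with BIO entity-type
    embeddings), screens predicted positives with five rule-based
    false-positive filters, and serves ranked triplet queries from an
    inverted index over the retained evidence. Includes a seeded
    synthetic-corpus generator with planted positive and negative
    sentence patterns so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
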
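Package: misuselex
Title: Detection of Drug Misuse in Patient Forum Messages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A multi-step text-mining pipeline for detecting drug misuse in
    French patient-forum messages. Enriches disorder seed-term lexica through
    morphological families, knowledge-base aliases, weighted relation graphs,
    Brown clustering and CBOW word embeddings, with Total/Vote combinations;
    indexes messages and sentences with disorder codes by lexicon matching;
    and categorizes messages into no-use, normal-use and misuse with
    in-repo Naive Bayes models, balanced sampling, a two-step cascade and
    entity-ablation feature studies. Includes evaluation primitives
    (precision/recall/F, Cohen's kappa with Landis-Koch bands) and a seeded
    synthetic-corpus generator with gold indexing and classification labels
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
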
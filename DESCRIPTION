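Package: rfab
Title: Risk-Factor Attention Networks for Cardiovascular Disease
    Prediction from Clinical Text
Version: 0.1.0
Authors@R:
    person("EMR", "Modeling Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage prediction of cardiovascular disease (CVD) from
    character-level electronic medical record (EMR) text. Stage one is a
    BiLSTM-CRF sequence tagger that identifies mentions of twelve CVD risk
    factors together with their time attributes (Before, During, After,
    Continue, None) under a BIO annotation scheme, with exact linear-chain
    CRF training and Viterbi decoding. Stage two is a risk-factor
    attention-based (RFAB) document classifier that fuses a character-level
    BiLSTM encoding of the full record with risk-factor embeddings via
    dot-product attention, then predicts a binary CVD label. Includes
    skip-gram pretraining of character embeddings augmented with a
    risk-factor dictionary, a synthetic-EMR corpus generator with gold
    annotations for offline end-to-end testing, entity-level and
    document-level evaluation metrics, attention-weight export, and a
    stage-oriented command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
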
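Package: crisprot
Title: Off-Target Propensity Prediction for CRISPR-Cas9 Guides with a
    GloVe-Initialised biLSTM-CNN
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts the off-target cleavage propensity of a single guide
    RNA (sgRNA) at candidate 23-nt genomic sites carrying 1-5 mismatches.
    Each sgRNA-DNA pair is tokenised into a length-23 vector over a
    16-symbol base-pair vocabulary, token vectors are learned with a GloVe
    co-occurrence embedding trained on the paired-sequence corpus, and a
    bidirectional LSTM followed by a five-layer 1-D convolutional network
    with classification (off-target yes/no) and regression (cleavage
    frequency) heads is trained with an imbalance-aware batch sampler.
    Includes leave-one-sgRNA-out evaluation, ranking and correlation
    metrics, a multiplicative CFD (Cutting Frequency Determination)
    baseline scorer, and a synthetic off-target dataset generator so the
    whole pipeline runs at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    seqinr
Config/testthat/edition: 3
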
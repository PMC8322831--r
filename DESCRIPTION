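Package: capstm
Title: Capsule-Network Text Matching for Short Question Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Trains and evaluates a five-layer capsule-network matcher that
    decides whether two short (medical) questions have the same intent. The
    architecture combines a highway-gated embedding transform, BiLSTM
    encoders, a cross-question attention interaction matrix, a convolutional
    capsule layer with iterative dynamic routing, and a sigmoid prediction
    head. All layers, their analytic gradients and the Adam training loop are
    implemented in vectorized base R, so models train at desk scale on a
    single CPU. Includes readers for TSV/JSONL question-pair corpora and
    word2vec-format vectors, a seeded synthetic paraphrase-pair generator
    with topic-swap hard negatives, ablation variants (max/mean pooling in
    place of routing, no attention), precision/recall/F evaluation, attention
    matrix export, broom-style tidiers and ggplot2 autoplot methods, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
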
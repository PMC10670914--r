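Package: swarmlayer
Title: Swarm-Intelligence Feature-Transform Layers for Two-Class Image Classification Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements swarm-intelligence optimizers (the Gorilla Troops
    Optimizer, a sine-cosine modified variant, Particle Swarm Optimization and
    Elephant Herding Optimization) as deterministic feature-to-feature
    transform layers that sit between a frozen feature extractor and a small
    trainable classifier head. Provides the full evaluation pipeline around
    the layer: two-class feature tables with CSV input/output, stratified
    70:15:15 train/validation/test splitting, two-stage hyperparameter grid
    search on validation accuracy, a batch-normalized dense softmax classifier
    head trained with Adamax, confusion-matrix metrics, and a synthetic
    generator emulating CNN embedding tables so the whole pipeline is testable
    without images or pretrained weights.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    readr,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
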
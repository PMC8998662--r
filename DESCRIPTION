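Package: promogan
Title: Feedback Wasserstein GAN for Promoter- and Motif-Tuned Synthetic DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic nucleic-acid sequences with a residual
    Wasserstein GAN trained under a gradient penalty, gated by a feedback
    loop: a convolutional promoter classifier decides which generated
    sequences look like promoters, and a position-weight-matrix evaluator
    scores them for motif matching before they reach the critic. Includes
    one-hot sequence encoding, FASTA and PWM input/output, synthetic
    training-data simulators, a metric suite for comparing original and
    synthetic sequence sets (Pearson correlation, MAE, RMSE, percent
    root-mean-square difference, mirror column association, discrete
    Frechet distance), classifier metrics with ROC support, stratified
    cross-validation, and latent-space tools (interpolation, gradient-based
    latent search, reflection-based complementation analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
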
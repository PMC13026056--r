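Package: eegdistill
Title: Dual-Teacher Knowledge Distillation for Motor-Imagery EEG
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains a single deployable convolutional decoder for
    motor-imagery EEG by distilling an offline K-fold bagging ensemble
    teacher together with an entropy-gated exponential-moving-average
    (EMA) teacher under a two-stage cosine-annealed learning-rate
    schedule. Includes a compact pure-R convolutional network engine
    (EEGNet- and ShallowConvNet-style reference backbones plus a tiny
    test network), temperature-scaled KL distillation losses with a
    per-sample predictive-entropy gate, epoch-wise entropy diagnostics
    (correct/wrong entropy trajectories, sliding-window entropy
    variance, subject-wise delta correlations), a synthetic oscillatory
    EEG generator for fully offline benchmarking, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
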
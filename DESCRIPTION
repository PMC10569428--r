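Package: wcapseq
Title: Weight-Capsule Sequence-to-Sequence Classification of ECG Heartbeats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inter-patient electrocardiogram (ECG) heartbeat classification
    with a weight-capsule network. Implements an MLP patch-mixing block with a
    skip concatenation, a capsule layer with a Sigmoid-squash compression
    function and weighted dynamic routing-by-agreement, and a bidirectional
    LSTM encoder / LSTM decoder sequence-to-sequence head that labels each
    beat of a sequence with its AAMI EC57 class (N, S, V, F, Q). Includes
    WFDB reading, the standard MIT-BIH inter-patient record splits and
    heartbeat extraction pipeline, per-class sensitivity/specificity/positive
    predictive value reporting, and a synthetic labeled-heartbeat generator
    with patient-level morphology structure so the full pipeline is testable
    without any external download. The networks are trained by a built-in
    reverse-mode automatic-differentiation engine with an Adam optimiser.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
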
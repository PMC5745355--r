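Package: puffdetect
Title: Hierarchical Detection of Smoking Sessions from Wrist Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects cigarette smoking sessions in triaxial smartwatch
    accelerometer recordings using a hierarchical model: a two-layer
    feed-forward neural network scores 5-second rolling windows for the
    hand-to-mouth puff gesture, and a rule-based layer above it assembles
    thresholded gesture streams into puffs and puff sequences into smoking
    sessions under timing constraints (minimum puff duration, inter-puff
    rest bounds, minimum puff count, maximum session duration). Includes
    zero-phase low-pass preprocessing, evaluation of detections against
    timestamped self-report logs (imputation of partial entries,
    overlap matching, true/false positive rates with progressive
    exclusion accounting), and a synthetic signal generator that produces
    20 Hz traces with ground-truth smoking sessions, confounder activities
    (eating, drinking, walking, typing, tying shoes), and self-report logs
    with injectable error modes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
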
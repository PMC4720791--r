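Package: brainswitch
Title: Short-Latency EEG Brain-Switch Simulation, Morphology and Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying short-latency detection of motor intention
    from scalp EEG. Simulates seeded motor-imagery sessions (ballistic and
    repetitive imagined dorsiflexion) with known movement-related cortical
    potential (MRCP) and sensorimotor-rhythm (SMR) content over a nine-channel
    10-20 montage; derives the virtual Cz channel with a large Laplacian
    spatial filter; reproduces MRCP significance profiles (paired t-tests with
    Holm-Bonferroni correction) and ERD/ERS time-frequency maps (Welch power,
    relative SMR power, bootstrap significance); and runs the full brain-switch
    detection comparison - time-series locality-preserving-projection LDA
    versus subband-power LDA - under a pseudo-online sliding-window protocol
    with consecutive-window triggering, latency-based true/false-positive
    scoring, and false-positive-constrained calibration of the required
    window count, evaluated by run-wise three-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
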
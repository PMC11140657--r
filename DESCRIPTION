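Package: sleeptmr
Title: Sleep EEG Analysis for Targeted Memory Reactivation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for targeted-memory-reactivation (TMR) sleep
    studies: individualized sleep-spindle and slow-oscillation detection,
    slow-oscillation/spindle phase coupling, cue-locked Morlet time-frequency
    and spindle-probability statistics with cluster-based permutation
    correction, REM theta power, and emotional-memory trade-off scoring.
    Includes a synthetic-session generator with known ground truth for
    validating every stage, plus readers for EDF and BrainVision recordings,
    hypnograms and cue logs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
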
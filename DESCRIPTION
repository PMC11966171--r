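Package: roughspeech
Title: Synthesis and Intelligibility Scoring of Speech with Nonlinear Vocal Phenomena
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how nonlinear vocal phenomena (subharmonics,
    amplitude modulation, jitter-based "chaos", frequency jumps and whisper)
    affect speech intelligibility. Provides parametric source-filter voice
    synthesis (additive harmonics with spectral rolloff, formant filtering,
    diphthong morphing, spectral/amplitude envelope transplantation, dynamic
    compression), source-level nonlinear-phonation manipulations applied
    continuously or in stochastic episodes, masking-noise generation and
    SNR mixing, reproducible stimulus manifests for three listening
    experiments, intelligibility metrics (digit matching, symbol-level DTW,
    word error rate, Levenshtein and Jaro distances), psychometric-curve
    fitting with 50% discrimination thresholds and bootstrap confidence
    intervals, and a synthetic-listener simulator so the whole pipeline runs
    without external recordings or human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
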
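Package: vocalmct
Title: Vocal Biomarkers of Bronchoconstriction During Methacholine Challenge
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for screening smartphone-style respiratory and vowel
    recordings for vocal biomarkers of airway narrowing. Recordings taken at
    each step of a methacholine challenge test are quality-gated, segmented
    into labeled breathing and phonation events, and summarised by 40 acoustic
    parameters per event (timing, spectral moments, flatness, roll-off, slope,
    linear prediction and mel-frequency cepstral coefficients) after a
    resonance-enhancing spectral compression. Per sound type the parameters
    are aggregated into 80 mean/variation biomarkers whose traces across
    challenge steps are correlated against the subject's FEV1 trace to rank
    and select per-subject best biomarkers. Includes a dose-response protocol
    simulator with PD20 dosimetry and a seeded synthetic-cohort generator that
    couples audio resonance structure to FEV1, so the whole pipeline is
    verifiable end-to-end without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
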
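Package: pupsyntax
Title: Temporal and Syntactic Analysis of Rat Pup Ultrasonic Vocalizations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for isolation-induced ultrasonic vocalizations
    (USVs) of rat pups in neurodevelopmental studies. Detects calls on
    spectrograms by spectral-entropy analysis, extracts acoustic features
    (peak frequency, bandwidth, duration, slope) from frequency contours,
    assigns calls to an eight-cluster taxonomy by transparent acoustic rules,
    segments call trains into sequences and bouts by inter-call-interval
    thresholds, builds within-bout cluster-transition ("syntax") models, and
    runs permutation-based group contrasts for developmental and maternal
    potentiation designs with litter-aware resampling. A seeded synthetic
    cohort generator with ground-truth sidecars makes every stage testable
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    signal,
    jsonlite
Config/testthat/edition: 3
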
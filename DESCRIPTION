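Package: optrepair
Title: Low-Rank Matrix Completion Repair of Artifacts in Multichannel
    Electrophysiology Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Repairs artifact-corrupted entries of multichannel neural
    recordings (EEG/MEG/LFP) by blockwise low-rank matrix completion:
    trimmed singular-value-decomposition initialization followed by
    gradient descent on a pair of orthonormal factor matrices (an
    OptSpace-style algorithm).  Includes an end-to-end repair pipeline
    (threshold-based artifact marking, channel/timepoint rejection,
    epoching, per-block completion, zero-phase band-pass filtering), a
    surrogate-artifact benchmarking framework with block libraries,
    severity quantiles and bootstrapped hyperparameter sweeps, a
    spherical-spline interpolation comparator, downstream event-related
    potential and between-trial variability analyses, and a seeded
    synthetic-data generator producing low-rank recordings and bursty
    artifact masks for testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
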
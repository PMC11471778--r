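Package: trfpac
Title: Temporal Response Functions and Phase-Amplitude Coupling for
    Continuous Neural Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward encoding models (temporal response functions, TRFs)
    estimated by closed-form ridge regression for continuous multichannel
    neural recordings during naturalistic speech listening, together with a
    complex-valued TRF method that generalises inter-trial phase clustering
    (ITPC) and phase-amplitude coupling (PAC) to continuous recordings and
    attributes cross-frequency coupling to word-level stimulus features.
    Includes word-level stimulus representations (constituency-tree depth and
    closing-node counts, surprisal, entropy, acoustic envelope, onset combs),
    band-limited analytic-signal construction, Morlet time-frequency
    decomposition, stimulus-wide PAC with surrogate z-scoring,
    cerebro-acoustic coherence, cluster-based permutation statistics, and a
    seeded synthetic-data module that simulates convolutional responses and
    three feature-dependent PAC scenarios for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils-dsp.R'
    'synthetic.R'
    'features.R'
    'envelope.R'
    'trf.R'
    'spectral.R'
    'crossfreq.R'
    'stats.R'
    'io.R'
    'studies.R'
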
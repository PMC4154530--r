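Package: sleepstager
Title: Sleep Stage Classification from Two-Channel Forehead EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic classification of sleep stages (W, N1, N2, N3, REM)
    from the two forehead EEG channels FP1 and FP2. Implements a
    knowledge-based spectral feature extractor built from short-time Fourier
    segments of each 30-s epoch, a sparse Bayesian (relevance vector machine)
    kernel classifier with one-against-all multiclass wrapping, baseline
    classifiers (LDA, k-NN, optional SVM), Fisher-criterion separability
    measures, leave-one-subject-out evaluation with Cohen's kappa, EDF and
    hypnogram file I/O, and a seeded synthetic sleep-EEG simulator encoding
    AASM scoring rules (alpha rhythm, spindles, K-complexes, slow waves,
    eye movements) for end-to-end testing without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
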
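Package: emgdecoder
Title: Online Decoding of Hand Posture and Digit Forces from Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an online myoelectric decoding pipeline for
    prosthetic hand control: preprocessing of multichannel forearm surface
    EMG (non-overlapping 50-ms windows, maximum-voluntary-contraction
    normalization, 60-Hz IIR notch filtering, threshold-based rest
    detection), time-domain spectral-moment feature extraction with
    pairwise channel expansion and correlation-based feature selection,
    a one-vs-one radial-basis-kernel SVM posture classifier with majority
    voting, per-digit random-forest force regression, sign-pattern pose
    logic, closed-loop task simulation for grasping and force-shifting
    protocols, and the associated evaluation statistics (confusion
    matrices, normalized grip-force RMSE, finger force fractions and the
    force distribution index, unwanted-opening rate). Ships a seeded
    synthetic EMG/force session generator so the full pipeline can be
    trained and evaluated without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    randomForest,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
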
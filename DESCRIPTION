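Package: physioplay
Title: Multimodal Physiological Analysis of Interactive Versus Passive Gameplay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An event-based pipeline for analysing multichannel peripheral
    physiology (ECG, electrodermal activity, respiration, EMG and skin
    temperature sampled at 1000 Hz) recorded while participants actively play
    or passively watch an emotionally challenging game scenario. Provides a
    seeded synthetic-cohort generator with per-channel ground truth, event
    segmentation, per-modality signal conditioning (Pan-Tompkins QRS
    detection, zero-phase Butterworth filtering, breath-cycle detection,
    EMG decimation), a canonical 80-feature extractor over non-overlapping
    10-s windows (HRV time and frequency domain, respiratory, temperature,
    EDA band analysis, 6-level db5 wavelet EMG energies), Benjamini-Hochberg
    corrected group comparisons, and participant-wise 10-fold cross-validated
    ridge logistic discrimination with modality ablations and single-feature
    screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
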
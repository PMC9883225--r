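Package: pcgpah
Title: Heart-Sound Screening for CHD-Related Pulmonary Arterial Hypertension
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phonocardiogram (PCG) analysis pipeline for non-invasive
    three-class screening of normal hearts, congenital heart disease (CHD),
    and CHD-related pulmonary arterial hypertension (CHD-PAH). Implements
    double-threshold adaptive segmentation of heart sounds into labelled
    S1/systole/S2/diastole intervals, time- and frequency-domain feature
    extraction from each cardiac cycle and its S2 component,
    power-normalized (PNCC) feature images with a small convolutional
    network as a 64-dimensional deep-feature extractor, gradient-boosted
    three-class classification of the fused feature vector, and
    record-level majority voting. A synthetic-PCG simulator with exact
    ground-truth annotations supports end-to-end testing without clinical
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    xgboost,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
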
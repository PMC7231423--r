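Package: spectroseize
Title: Cross-Subject Seizure Detection from EEG Time-Frequency Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end pipeline for cross-subject epileptic seizure
    detection from scalp EEG. Reads European Data Format (EDF) recordings and
    CHB-MIT-style seizure annotations, generates labeled synthetic multichannel
    EEG for fully offline testing, segments records with a 180-second sliding
    window (30% overlap) plus one-second-step augmentation of seizure
    intervals, converts each three-channel segment to a fused 224x224x3
    time-frequency image via the short-time Fourier transform, builds shuffled
    60/20/20 train/validation/test splits, trains frozen-backbone transfer
    classifiers with configurable fully connected heads, and evaluates them
    with accuracy, recall, precision and the Matthews correlation coefficient,
    including reconstruction of confusion counts from printed rates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    jsonlite,
    yaml,
    png,
    withr
Suggests:
    testthat (>= 3.0.0),
    signal
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'edf.R'
    'annotations.R'
    'synthetic.R'
    'segmentation.R'
    'stft.R'
    'tfimage.R'
    'dataset.R'
    'model.R'
    'train.R'
    'metrics.R'
    'cli.R'
    'spectroseize-package.R'
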
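Package: noduleclip
Title: Semantic-Guided Vision-Language Modeling of Lung Nodule Malignancy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns 2.5D multi-view CT renderings of lung nodules with
    report-like text derived from radiologist semantic features, using a
    contrastively trained dual transformer encoder with low-rank adapters and
    attention-based multiple-instance pooling over nine planar views. Produces
    calibrated one-year cancer risk at the nodule and patient level (Beta
    calibration, cross-validated ensembling) and zero-shot semantic-feature
    predictions from prompt banks. Includes CT preprocessing (isotropic
    resampling, HU windowing, nine-plane view extraction, volumetric
    augmentation), a deterministic report templater, rarity-upsampling
    patient-level training, ranking and calibration metrics with bootstrap
    intervals, and a seeded phantom-cohort generator whose rendered nodule
    morphology encodes sampled semantic records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
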
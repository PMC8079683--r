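Package: radcal
Title: Calibrated Convolutional Ensembles for Musculoskeletal Radiograph
    Abnormality Detection
Version: 0.1.0
Authors@R:
    person("radcal", "maintainers", email = "maintainers@radcal.dev",
           role = c("aut", "cre"))
Description: Tools for detecting abnormalities in multi-view musculoskeletal
    radiograph studies with convolutional neural networks. Provides manifest
    and image ingestion for the seven standard upper-extremity regions,
    declarative builders for three baseline architectures (a VGG-style
    ConvNet, a full pre-activation ResNet, and a DenseNet configuration), a
    class-weighted cross-entropy loss for per-region class imbalance,
    study-level decisioning, five evaluation metrics with percent-change
    tables, a calibrated per-region learner-designation rule with routed
    prediction, class activation maps, and a seeded synthetic radiograph-study
    generator so the full pipeline runs at desk scale on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    png,
    yaml,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
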
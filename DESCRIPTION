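Package: phasefall
Title: Hierarchical Fall Detection from Tri-Axial Accelerometry with a
    Multiphase Fall Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects falls in waist-worn tri-axial accelerometer recordings
    using a two-stage hierarchical classifier.  Records are windowed into
    fixed 513-sample frames around the acceleration-norm peak; a learned
    four-threshold rule triages frames into absolute falls, absolute
    activities of daily living (ADLs), and an unidentified band; frames in
    the band are segmented into free-fall, impact, and rest phases, each
    phase is described by 54 time-domain statistics, and a one-vs-one
    linear support vector machine labels the phases, with a fall declared
    only when the phases occur in free-fall, impact, rest order.  Includes
    the evaluation protocol (confusion matrices, sensitivity/specificity/
    precision/accuracy, repeated stratified k-fold cross-validation), a
    synthetic accelerometer signal simulator with per-sample phase ground
    truth, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
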
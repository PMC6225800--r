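Package: kneestudy
Title: Radiographic Features of Knee Osteoarthritis and Their Relation to Knee Pain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating radiographic features of knee osteoarthritis to
    frequent knee pain. Provides a synthetic radiograph cohort generator with
    known ground truth (latent disease severity driving image geometry, ordinal
    reader-style grades, repeated binary pain reports and demographics),
    point-distribution shape models with generalized Procrustes alignment,
    combined shape and texture (appearance) models sampled in a
    shape-normalized frame, fully automatic landmark localization by
    constrained local models with regression-voting response maps, derivation
    of single-report and consistent-pain outcomes with a widespread-pain
    exclusion, and a repeated cross-validated random-forest evaluation engine
    reporting AUC with paired DeLong-type chi-square comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
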
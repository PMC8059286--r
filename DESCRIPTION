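Package: iolstrat
Title: Gender-Stratified Lens Constant Optimization for Intraocular Lens
    Power Formulas
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements four classical vergence-based intraocular lens (IOL)
    power formulas (SRK/T, Holladay 1, Hoffer Q, Haigis) as refraction
    predictors, lens-constant optimization by zeroization of the mean signed
    prediction error (pooled and stratified by gender), and the cohort
    analysis pipeline around them: record validation, prediction-error
    outlier exclusion, patient-level train/test splitting with one test eye
    per patient, per-formula signed and absolute prediction-error summaries,
    nonparametric and parametric group comparisons, and prediction-error
    regression. A seeded synthetic biometry cohort generator with known
    ground truth (true lens constants, gender-specific refraction offsets,
    refraction noise) makes every pipeline stage testable without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    MASS,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
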
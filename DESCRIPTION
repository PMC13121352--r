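Package: rootstress
Title: Soybean Root Elongation Under Combined Soil Mechanical and Hydric Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-empirical modelling of soybean primary-root elongation as a
    function of soil penetration resistance (mechanical stress) and degree of
    water saturation (hydric stress) in intact (Field) and re-packed (Packed)
    soil structures. Provides soil physical-state derivations (porosity,
    volumetric water content, saturation degree, degree of compactness),
    Busscher power-law fitting of penetration resistance against bulk density
    and water content, three-dimensional Gaussian response-surface fitting of
    relative root elongation, model agreement metrics (RMSE, CRM, Pearson r,
    Willmott d) with a stratified fit/validation split, and a seeded synthetic
    experiment generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
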
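Package: vfarch
Title: Archetypal Analysis of Binocular Visual Field Loss
Version: 0.1.0
Authors@R:
    person("vfarch", "maintainers", email = "vfarch@example.org", role = c("aut", "cre"))
Description: Tools for studying patterns of binocular visual field (BVF) loss
    in glaucoma and their relation to vision-related quality of life.
    Integrates paired monocular Humphrey 24-2 perimetry tests into a binocular
    field by quadratic summation, applies reliability filtering and a
    homonymous-defect screen, learns archetypes of BVF loss by alternating
    simplex-constrained least squares with cross-validated BIC model-order
    selection, decomposes individual fields into archetype weights, and
    relates weights to ordinal questionnaire outcomes through
    proportional-odds regression. Includes a fully specified synthetic-data
    generator so every stage can be exercised and validated without access to
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    optparse
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    quadprog
Config/testthat/edition: 3
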
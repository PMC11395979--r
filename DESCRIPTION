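Package: coameta
Title: Morphometry-to-Hemodynamics Metamodeling for Pediatric Aortic Coarctation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to relate landmark diameters of the pediatric thoracic aorta
    to landmark blood velocities and pressures, and to classify aortas as
    normal versus coarctation (CoA). Includes automatic morphometry on vessel
    surface meshes (STL), chained ratio-feature surrogate regressions that
    stand in for computational fluid dynamics at the landmark level, logistic
    classifiers on morphometric, hemodynamic and surrogate-predicted features,
    and a synthetic cohort generator built on a squared-diameter flow-balance
    model for end-to-end evaluation when patient data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
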
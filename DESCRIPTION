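Package: onhmorph
Title: Optic Nerve Head Morphometrics from Segmented OCT Geometry
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Computes Bruch's membrane opening (BMO) morphometrics (ovality
    index, tilt angle, rotation angle, BMO area), BMO minimum rim width, and
    circumpapillary retinal nerve fiber layer and peripapillary choroidal
    thickness with Garway-Heath sectorization from segmented OCT radial and
    circle scans. Includes a seeded synthetic scan-geometry generator with
    known ground truth, eye-level linear mixed-model cohort statistics with
    Satterthwaite degrees of freedom and Edwards semi-partial R-squared, and
    an end-to-end simulation pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    lmerTest,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
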
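Package: osteoinertia
Title: Inertia-Based Positioning and Sex Estimation from Metatarsal CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for forensic osteometry from CT density volumes. Positions a
    segmented bone in a body coordinate system defined by its center of mass and
    principal axes of inertia, extracts eight geometric and inertial variables
    (normalized length, width, height, surface-area-to-volume ratio, bone density,
    and three normalized principal moments of inertia), computes cohort-level
    sexual-dimorphism statistics (dimorphism index, test dispatch with normality
    and homoscedasticity checks, multivariate assumption battery, intraclass
    correlation), and fits two-group stepwise discriminant functions gated by
    partial-F thresholds on Wilks' lambda, with leave-one-out validation and a
    registry of published metatarsal sex-estimation functions. Includes voxel
    phantoms with closed-form mass properties and a cohort simulator for
    validation without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    RNifti,
    car,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
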
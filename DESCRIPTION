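Package: chewsim
Title: Kinematic-Dynamic Simulation of Unilateral Chewing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale kinematic-dynamic simulator of unilateral chewing.
    Given a food's force-deformation characteristic and height, the package
    prescribes an ellipse-like chewing path for the incisal point, solves the
    inverse kinematics of the mandible under temporomandibular joint contact
    constraints, solves the quasi-static equilibrium for the mandibular
    elevator muscle forces (masseter, medial pterygoid, temporalis) on the
    working and non-working sides, decomposes the temporalis principal vector
    into anterior, middle and posterior components, and derives per-muscle
    summaries: maximum force, contractions, stiffness, intrinsic strength and
    proportionality coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
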
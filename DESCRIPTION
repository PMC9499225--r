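Package: ommatidics
Title: Compound-Eye Optics and Cuticle-Color Comparative Analysis for Ants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative visual ecology of ants: geometric
    estimators of compound-eye optics from digitized eye-edge profiles
    (interommatidial angle by the radius-of-curvature construction, visual
    field span, eye parameter, facet area), a cuticular-brightness
    measurement protocol with pale/dark classification, covariate-adjusted
    comparative statistics (MANCOVA/ANCOVA with estimated marginal means,
    compact letter displays, assumption checks, repeated-measures ANOVA
    with sphericity testing, exact r x c contingency tests), packaged
    species-level morphometric tables, synthetic data generators for
    validation, and an end-to-end reproduction pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    car,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    knitr,
    rmarkdown
Config/testthat/edition: 3
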
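Package: orthomotion
Title: Designed Versus Achieved 3D Tooth Movement Analysis for Clear-Aligner Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how closely achieved orthodontic tooth movement matches
    the virtual setup in premolar-extraction clear-aligner treatment, using 3D
    whole-tooth (crown plus root) models. Provides rigid best-fit (ICP)
    superimposition of maxillary models on the bone surface, landmark-defined
    world and per-tooth coordinate frames, projected mesiodistal/buccolingual
    angular and linear movement metrics with anatomical sign conventions,
    designed-minus-achieved differencing, and the cohort statistics layer
    (paired t-tests, two-way absolute-agreement ICC, linear mixed models of
    influencing factors). A synthetic maxillary-arch generator with a
    machine-readable truth manifest makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
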
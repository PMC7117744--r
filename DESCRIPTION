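Package: habrep
Title: Repeatability-Based Analysis of Behavioral Habituation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding how long laboratory animals should be habituated
    to a test apparatus before an experiment starts. Repeated open-field
    measurements (one trial per day) are decomposed with Gaussian linear mixed
    models fitted by restricted maximum likelihood into variance attributable to
    individual animals, strain, and experimental batch. Agreement and adjusted
    repeatability (intraclass correlation) are reported with parametric-bootstrap
    confidence intervals, permutation p-values, and boundary-corrected
    likelihood-ratio tests. A sliding-window scan over adjacent trial days
    locates when stable between-individual differences emerge and converts the
    window series into a recommended habituation length. A synthetic-data module
    generates habituation datasets with known ground truth (novelty decay,
    late-emerging individual intercepts, strain and batch components) so every
    stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
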
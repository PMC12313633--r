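Package: droughtmet
Title: Multi-Environment Evaluation of Germplasm for Drought Tolerance
Version: 0.1.0
Authors@R:
    person("droughtmet", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Two-stage mixed-model analysis of augmented randomized
    complete block (ARCBD) multi-environment trials as used in germplasm
    screening for reproductive-stage drought tolerance: single-trial BLUEs
    with REML variance components and broad-sense heritability, across-
    environment BLUPs, stress-induced trait reduction metrics, trait and
    environment correlations, stepwise regression of grain yield on
    secondary traits, check-anchored drought-tolerance classification, and
    a desired-gain multi-trait selection index. Includes a synthetic plot-
    level data generator with known ground truth for validating every
    stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
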
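Package: regcap
Title: Composite-Indicator Evaluation of Provincial Drug-Regulatory Capacity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds two-level composite indicators of provincial drug-regulatory
    capacity from panel data: min-max normalization of positive and negative
    indicators, subjective weighting from expert importance scores, objective
    entropy weighting, combined subjective-objective weights, dimension and
    composite scores with competition ranking, one-way ANOVA across economic
    belts, obstacle-degree diagnosis of limiting indicators, and descriptive
    pharmacovigilance series. Includes a synthetic panel generator with known
    latent structure for calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
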
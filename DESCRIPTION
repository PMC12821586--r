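Package: quasicw
Title: Correlation-Weighted Quasi-SMILES Models for Condition-Dependent Toxicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds optimal-descriptor QSAR models from quasi-SMILES, i.e.
    SMILES strings augmented with categorical codes for experimental and
    environmental conditions (species, life stage, exposure duration,
    persistence bins). Attribute correlation weights are learned by Monte
    Carlo hill climbing against target functions with or without the Index
    of Ideality of Correlation, the endpoint is modelled by a univariate
    linear regression on the summed weights, and models are validated with
    a standard battery (determination coefficient, concordance correlation
    coefficient, leave-one-out Q2, Roy-Kar metric, MAE, Fisher ratio), a
    statistical-defect applicability domain, and a promoter analysis over
    replicate runs. Includes a synthetic quasi-SMILES generator with
    planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
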
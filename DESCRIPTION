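Package: encmediate
Title: Women's Empowerment, Skilled Antenatal Care and Essential Newborn Care Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how a multidimensional women's empowerment
    index (MEI) relates to good essential newborn care (ENC) practice with
    skilled antenatal care (SANC) as a mediator. Provides Alkire-Foster style
    composite-index scoring with a configurable dimension/indicator schema,
    derivation of the binary good-ENC outcome and the eight-plus-visit SANC
    mediator, random-intercept logistic regression with latent-scale
    intraclass correlation and boundary-corrected likelihood-ratio tests,
    product-of-coefficients mediation with cluster-bootstrap bias-corrected
    confidence intervals, covariate screening, descriptive association
    tables, and a synthetic generator for clustered DHS-like survey data
    with known ground truth so the whole pipeline is testable without
    restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
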
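Package: btcoi
Title: Cost-of-Illness Analysis of Bt Cotton Adoption and Farmer Health
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the pesticide-related health costs of
    cotton farmers under uncertain Bt seed quality. Implements a synthetic
    farm-survey generator with lab-versus-belief adoption misclassification,
    laboratory-based adoption classification from strip tests and ELISA Bt
    toxin expression, cost-of-illness construction (direct treatment costs
    plus work days lost valued at the wage rate), maximum-likelihood
    estimation of Cragg's double-hurdle model (probit first hurdle,
    zero-truncated normal second hurdle) and the nested Tobit alternative
    with a likelihood-ratio specification test, conditional and
    unconditional average marginal effects with bootstrap standard errors,
    and national extrapolation of health-cost savings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite
Config/testthat/edition: 3
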
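Package: hcineq
Title: Concentration Indices and Decomposition of Socioeconomic
    Inequality in Health Care Utilisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures socioeconomic-related inequality in binary health care
    utilisation outcomes from survey microdata. Computes weighted fractional
    income ranks, concentration curves, and the standard, Erreygers-corrected
    and Wagstaff-corrected concentration indices with robust-regression or
    clustered-bootstrap confidence intervals; decomposes the corrected index
    into covariate contributions through a probit model with averaged partial
    effects and generalized concentration indices; and drives end-to-end
    studies (eligibility filtering, prevalence, indices by stratum,
    decomposition tables) over real or simulated survey waves. Includes a
    synthetic household-survey generator with a fully known latent
    utilisation model for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    sandwich
Suggests:
    arrow,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
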
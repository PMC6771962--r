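Package: rfduq
Title: Quantitative Uncertainty Deconstruction of Toxicological Reference Doses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deconstructing a chronic oral reference dose (RfD) into
    its quantitative ingredients and re-deriving it under alternative
    assumptions. Implements deterministic RfD arithmetic (uncertainty-factor
    composition, point-of-departure handling, unit conversion, presentation
    rounding, anchored serum-to-intake scaling), toxic-equivalency (TEQ)
    accounting for dioxin-like mixtures, significance screening and
    NOAEL/LOAEL classification from published group summary statistics,
    log-log calibration regression with inverse prediction and Massart-style
    or Fieller 95% confidence bounds on the exposure at an outcome threshold,
    Bayesian "induced prior" RfD distributions built from lognormal
    uncertainty-factor priors with closed-form lognormal algebra and Monte
    Carlo sampling, and a deterministic sensitivity-tree ensemble of plausible
    RfD values. Includes seeded synthetic-data generators emulating a small
    mother-infant serum-dioxin/neonatal-TSH cohort and quartile summary
    tables, so every pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
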
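Package: stabmeta
Title: Multilevel Meta-Analysis of Yield Variability in Pollination Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for meta-analysis of variability in crop pollination
    exclusion experiments. Computes small-sample bias-corrected ratio
    effect sizes (lnRR, lnVR, lnCVR) and arm-based ln(SD) rows from
    two-arm summary data, models correlated sampling errors from shared
    control groups with a block variance-covariance matrix, and fits
    multilevel (publication / comparison / effect-size) random-effects
    meta-analytic models by REML or ML with Wald inference, prediction
    intervals, likelihood-ratio tests, cluster-robust (CR2) variance
    estimation, multilevel I-squared and marginal R-squared. Includes
    the full model suite used for yield-stability analyses, sensitivity
    analyses (leave-one-out, effect-size subsampling, time-lag and
    Egger-type regressions), and seeded synthetic-data generators,
    including a mechanistic resource-ceiling simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), metafor, withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
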
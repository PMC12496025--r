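Package: carebundles
Title: Provider Incentives and Policy Evaluation of Care-Bundle Pay-for-Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying pay-for-performance schemes that condition a
    single bonus payment on an all-or-nothing bundle of care processes, in the
    setting of the English Best Practice Tariff for fragility hip fracture.
    Provides a microsimulation of provider decisions under bundled versus
    itemized payment with cost synergies; a calibrated synthetic generator of
    patient-level hip-fracture audit records with correlated binary care-process
    indicators; and a from-scratch difference-in-differences estimation pipeline
    built on a linear probability model with absorbed hospital fixed effects and
    cluster-robust (sandwich) covariance, including period-specific effects,
    pre-trend (parallel-trends) tests, per-criterion effects, robustness
    variants, and a sequential decision-making analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    mvtnorm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
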
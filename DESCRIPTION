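Package: adrtrend
Title: Growth-Curve Modelling and Trend-Based Ranking of Adverse Drug
    Reaction Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trend-based pharmacovigilance on annual adverse drug
    reaction (ADR) report counts, as exported from public dashboards such as
    the FDA Adverse Event Reporting System (FAERS) or VigiAccess. Cumulative
    reporting curves are fitted with four growth families (linear,
    exponential, shifted Michaelis-Menten saturation, logistic), each drug's
    temporal pattern is classified by information-criterion model selection,
    and drugs are ranked by the Detriment Index: the exponential growth-rate
    parameter beta of Y(t) = alpha * exp(beta * t), a scale-invariant measure
    of how fast safety signals accumulate. A seeded simulator generates
    synthetic report series with known generating parameters for recovery and
    classification studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
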
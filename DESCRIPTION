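Package: strokeCEA
Title: Cost-Effectiveness of Reperfusion Quality After Endovascular
    Thrombectomy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision-analytic modelling of the lifetime health-economic
    consequences of incomplete reperfusion after endovascular thrombectomy
    (EVT) for large-vessel-occlusion stroke. Implements a two-phase Markov
    cohort model over modified Rankin Scale (mRS) health states: a 3-month
    short-run phase ending at the 90-day mRS distribution of a reperfusion
    pattern (eTICI grade), followed by annual cycles with recurrent stroke,
    functional deterioration and age-dependent mortality. Accrues
    quality-adjusted life years and costs under healthcare and societal
    (human-capital) perspectives, performs base-case incremental
    cost-effectiveness analysis (ICER, dominance, net monetary benefit),
    second-order Monte Carlo probabilistic sensitivity analysis with
    acceptability at willingness-to-pay thresholds, and population-level
    budget impact scaling. Includes synthetic generators for trial-like
    cohorts, life tables and parameter tables so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
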
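Package: tdm1cea
Title: Cost-Effectiveness of Adjuvant T-DM1 in HER2-Positive Early Breast
    Cancer with Residual Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Markov cohort state-transition model evaluating adjuvant
    trastuzumab-emtansine (T-DM1) against trastuzumab in HER2-positive early
    breast cancer with residual invasive disease after neoadjuvant therapy.
    Provides mixture-cure parametric survival extrapolation with
    treatment-effect waning, a monthly-cycle cohort engine with tunnel states
    and half-cycle correction, micro-costing and QALY accumulation with
    ICER/NMB summaries, deterministic (tornado) and probabilistic sensitivity
    analysis with CEAC, and a synthetic trial-data generator emulating
    two-arm invasive-disease-free survival with a cured fraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    flexsurv,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
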
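Package: selstop
Title: Simulation and Bayesian Analysis of Response-Selective Stopping Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the multicomponent (bimanual) stop-signal task with
    reactive and proactive cueing. Provides a deterministic trial-schedule
    builder with pseudorandomized TMS allocation, an independent race model
    simulator with staircased stop-signal delays and synthetic EMG/MEP
    records, the standard behavioural processing rules (fast-guess filtering,
    Table-style task summaries, SSRT estimation by the integration method
    with validity exclusions), MEP peak-to-peak extraction with
    pre-stimulus EMG exclusion and hand-status labelling, and Bayesian
    mixed-model contrasts (shifted-lognormal, Gaussian, Gamma log-link and
    Bernoulli logistic families) summarised with the probability of
    direction, 89% highest-density intervals and an HDI+ROPE decision rule.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    dplyr,
    jsonlite,
    rjags,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
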
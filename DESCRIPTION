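Package: pestresurge
Title: Pest Resurgence Dynamics Under Pesticide Application Regimes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates season-long transient dynamics of arthropod pests and
    their natural enemies under four pesticide application regimes (pulsed,
    frequency-varied, threshold-triggered and continuous), using a
    Rosenzweig-MacArthur predator-prey model and a bioenergetic tritrophic
    food-web model with optional alternative prey. Provides season summaries
    (time-averaged densities, cumulative-average crossover, resurgence
    intervals, predator extinction), parameter sweeps over pesticide mortality,
    application frequency and selectivity, and a meta-analytic toolchain
    (Hedges g effect sizes, multilevel random-effects meta-regression with
    moderators, continuous-time autoregressive serial structure,
    cluster-robust inference and likelihood-ratio moderator tests) together
    with synthetic virtual field-trial generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite
Config/testthat/edition: 3
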
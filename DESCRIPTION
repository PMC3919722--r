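Package: evacdyn
Title: Behavioral Decision Dynamics in Collective Evacuation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis of laboratory-style collective
    evacuation experiments. Generates stochastic threat trajectories with
    per-second strike likelihoods, simulates networked agents competing for
    limited shelter under time pressure, estimates per-likelihood evacuation
    rates with a Beta posterior, fits Hill-function hazard-rate decision
    models (population, capacity-dependent, time-urgency-dependent, and
    per-individual) by count-level maximum likelihood, validates fits by
    run-level bootstrap and leave-one-out cross-validation, and
    forward-predicts collective evacuation curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
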
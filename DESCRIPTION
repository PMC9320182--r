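Package: aquarisk
Title: Heavy-Metal Pollution Indices and Ingestion-Pathway Health Risk for Domestic Water
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing heavy-metal(loid) contamination of domestic
    drinking water supplies: composite pollution indices (heavy-metal pollution
    index, single-factor pollution index, Nemerow index) against regulatory
    limits, USEPA-style ingestion-pathway exposure and risk metrics (chronic
    daily intake, hazard quotient and index, carcinogenic risk) for adult and
    child cohorts, Monte Carlo uncertainty propagation with
    contribution-to-variance sensitivity analysis, descriptive and correlation
    statistics with hierarchical clustering of metals, and machine-learning
    geostatistical interpolation of index surfaces (a neural-network trend
    trained by particle swarm optimisation plus residual ordinary kriging).
    Includes a synthetic sampling-campaign generator that emulates a
    three-source-type survey with lognormal concentration distributions and a
    smooth latent spatial field, so the whole pipeline is testable end to end.
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
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
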
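Package: plumefall
Title: Bayesian Gaussian-Process Mapping of Point-Source Lead Fallout in Soil
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the spatial footprint and integrated mass of
    a metal fallout event from a surface-soil survey around a point source.
    Surveys are expressed in source-centred polar coordinates and soil lead
    concentrations, quarter-power transformed, are modelled as a hierarchical
    Bayesian Gaussian-process regression: zero-sum soil-type offsets plus a
    latent spatial field with a product kernel (squared-exponential in
    distance, periodic in bearing) and Gaussian observational noise. The
    package provides MCMC fitting with convergence diagnostics,
    posterior-predictive reconstruction of the concentration field on a polar
    grid, sector-based plume-excess profiles, area-weighted average excess
    concentrations, integrated excess-mass inventories with credible
    intervals, unit conversions between soil concentration and areal loading,
    and a synthetic-survey generator with known ground truth for calibration
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    stats,
    utils
Suggests:
    geosphere,
    jsonlite,
    mvtnorm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
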
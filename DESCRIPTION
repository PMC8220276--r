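Package: birdflux
Title: Quantifying Nocturnal Bird Migration as a Fluid Flow from Weather-Radar Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models broad-front nocturnal bird migration as a conserved fluid.
    Vertical profile time series from weather radars are cleaned and vertically
    integrated into per-radar areal densities and velocities, interpolated onto a
    latitude-longitude-time lattice by spatio-temporal kriging with conditional
    Gaussian simulation for uncertainty, and fed to a flow model that inverts the
    discretized continuity equation for the take-off/landing source/sink term and
    the fluxes through the domain boundary. Aggregation operations deliver nightly
    take-off and landing maps, year-round accumulation of birds on the ground, and
    seasonal flows through named boundary transects, each with ensemble quantile
    uncertainty. A synthetic scenario generator evolves planted take-off/landing
    pulses forward with the same stencil so that every inference stage has an
    exact recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    ggplot2,
    readr,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
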
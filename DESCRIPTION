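Package: ringmorph
Title: Continuous Attractor Ring Networks with Correlated and Morphed Maps
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing threshold-linear recurrent networks that
    store two correlated ring maps, or a morph sequence between two
    uncorrelated ring maps. Implements the exact five-variable mean-field
    (order-parameter) reduction of the rate dynamics, fixed-point solving
    and regime classification over the coupling/map-distance plane
    (homogeneous, single-ring, double-ring and cylinder regimes, amplitude
    instability), linear stability analysis, a finite-size microscopic
    rate-network simulator with order-parameter estimators, and the
    stimulation protocols used to probe the cylinder regime: tuning-curve
    estimation, dynamical pattern separation under moving inputs, a delayed
    shortest-path discrimination task, and slow-morph remapping with
    activity-correlation readouts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tools,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
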
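Package: shorewatch
Title: Shore-Based Cetacean Habitat-Use Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing land-based cetacean scan surveys around
    tidal islands and headlands: geolocation of reticle-binocular sightings
    from elevated platforms, distance-accumulation curves and detection
    filtering, terrain and tidal covariate engineering (including the
    log10(h/U^3) tidal stratification parameter), effort-balanced kernel
    density core areas with percent-volume contours, and presence/availability
    habitat models fitted as an inhomogeneous Poisson point process via
    infinitely weighted logistic regression with day-grouped cross-validated
    forward model selection.  A synthetic-study generator produces complete
    surveys (bathymetry, tidal currents, effort schedules and a thinned point
    process with known truth) for testing every stage end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    mgcv,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
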
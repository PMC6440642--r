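Package: srvolume
Title: Spatial Protection Volumes for Controlled-Release Mosquito Repellent Devices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An analysis pipeline for assessing the spatial protection
    efficacy of controlled-release devices that emit a volatile insecticide
    (e.g. metofluthrin). Estimates device release rates from formulation
    evaporation time series, simulates three-dimensional advection-diffusion
    transport of the active ingredient on a structured finite-volume grid
    with fans, enclosures and ambient wind, correlates simulated
    concentrations with caged-mosquito mortality through a linear
    dose-response model, and extracts the "protection bubble": the
    iso-surface-bounded volume where the time-averaged concentration meets
    the level associated with a target mortality. Includes a synthetic-data
    module that emulates semi-field tent and outdoor ring bioassay layouts
    so the whole pipeline can be exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
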
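Package: insoleGait
Title: Pressure-Sensitive Insole Signal Processing and Gait Event Detection
Version: 0.1.0
Authors@R: person("insoleGait", "Maintainers", email = "maintainers@insolegait.org", role = c("aut", "cre"))
Description: Signal-processing toolchain for optoelectronic pressure-sensitive
    insoles: polynomial force-to-voltage tactel calibration, per-frame
    estimation of the vertical ground reaction force (vGRF) and the
    antero-posterior center of pressure (CoP_AP), threshold-based real-time
    heel-strike/toe-off detection, a force-plate validation battery
    (event-timing median absolute errors, stance-normalized profile
    correlation and RMSE, repeatability, body-mass normalization), a sensor
    ranking/subset evaluation workflow for sensor-placement studies, and a
    seeded synthetic gait simulator so the whole pipeline can be exercised
    without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
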
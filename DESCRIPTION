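Package: powdershelf
Title: Moisture-Sorption Shelf-Life Modelling for Packaged Food Powders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the shelf life of low-moisture food powders
    stored in permeable packaging, built around spray-dried apricot powder as
    the worked system. Fits moisture sorption isotherms (GAB, Halsey, Oswin,
    Iglesias-Chirife), integrates the package moisture-balance ordinary
    differential equation driven by film water-vapour permeability, locates
    the time at which powder moisture reaches its critical value, and computes
    standard powder quality indices (degree of caking, Carr index and flow
    class, rehydration ratio, water-activity stability, total-plate-count
    limits). Includes a transcribed 180-day storage study (control and
    anticaking-agent treatments under ambient and accelerated conditions), a
    calibration pipeline for it, and a seeded synthetic storage-experiment
    generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
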
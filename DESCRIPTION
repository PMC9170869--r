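Package: cycloyield
Title: Cyclotron Radionuclide Production Modelling for Solid Targets
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the physics of medical-cyclotron radionuclide production on
    solid targets, with iodine-124 from tellurium dioxide as the worked case.
    Implements Bethe stopping power and continuous-slowing-down (CSDA) proton
    ranges in compound media, degrader-foil energy loss by range inversion,
    thick-target activation yields by integration of an excitation function
    over the in-target energy window, multi-nuclide decay-inventory evolution,
    and a pharmacopoeial radionuclidic-purity release-time solver. Ships
    calibrated synthetic excitation functions, randomized inventory
    generators, and reference datasets from a natural/enriched TeO2
    production campaign.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    tools,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
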
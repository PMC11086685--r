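Package: aerowheel
Title: Magnetic Microwheel Aerosol Delivery: Physics, Partition Statistics
    and Image Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models and analysis tools for in-situ-assembled magnetic
    microwheels delivered to the airway as bead-laden aerosol droplets.
    Implements the torque-balance model of microwheel rotation, power and
    rolling translation with its size scaling laws; lognormal droplet-size
    and Poisson bead-partition statistics for nebulized suspensions;
    seeded synthetic generators for droplet macroscan images and
    particle-tracking tables with ground truth; the droplet segmentation,
    bead detection and bead-to-droplet assignment pipeline; track
    filtering, scaling-law fits and susceptibility recovery; and a minimal
    branching-airway routing model for heading-controlled transport.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
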
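Package: selfright
Title: Potential Energy Landscapes and Energetics of Ground Self-Righting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models strenuous ground self-righting of overturned animals and
    robots as barrier-crossing transitions on a gravitational potential energy
    landscape over body pitch-roll space. Provides parametric self-deforming
    body models (ellipsoidal bodies with wing-like shell slices, legs, and
    internal components), exact ground-contact support heights, landscape and
    directional escape-barrier computation versus wing-opening angle,
    segment-wise pitch/roll kinetic energy from 3D marker tracks, geometric and
    dynamic (Froude) similarity metrics, normalized cross-correlation of
    kinematic signals, synthetic-data generators, and a stochastic
    barrier-crossing attempt simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
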
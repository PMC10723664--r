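Package: fastloctrack
Title: Movement Inference from Fastloc-GPS Telemetry of Benthic Sea Turtles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for inferring daily, seasonal, and migratory
    movements of benthic-stage sea turtles from Fastloc-GPS telemetry.
    Includes satellite-count/residual plausibility screening and iterative
    speed filtering of fixes, 12-h track re-discretization, penalized
    Gaussian dynamic-programming segmentation into stationary phases with
    Bhattacharyya-coefficient distinctness testing, kernel utilization
    distributions with a contiguity-based smoothing-parameter rule and
    25/50/90/95% isopleths, minimum convex polygons with asymptote checks,
    density-based discovery and classification of distinct use areas
    (foraging, resting, cool-weather refugia), diel and seasonal occupancy
    and binned-dive summaries, migration path metrics (3-position
    straightness, circular bearings, day/night travel rates), and
    net-capture detectability estimation. A central-place forager simulator
    generates ground-truthed tracks for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    mgcv,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
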
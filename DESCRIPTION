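Package: sheaftrack
Title: Sheaf-Based Consistency Analysis for Heterogeneous Geolocation Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying agreement among heterogeneous geolocation
    sensors using sheaves on abstract simplicial complexes.  Sensor streams
    (animal-borne GPS collars, vehicle GPS, VHF radio receivers, free-text
    location reports) are modelled as assignments to the vertices of a
    simplicial complex; restriction maps register every reading into a common
    coordinate frame so that disagreement can be measured face by face.  The
    package computes the consistency radius, maximal consistent subcomplex
    covers with their graded-poset rank measures, and the consistency
    filtration that attributes the overall uncertainty to specific sensor
    combinations.  A comparison dynamic linear model with Kalman filtering and
    maximum-likelihood variance estimation, a synthetic telemetry session
    generator, CSV/GeoJSON readers and writers, and a small command-line
    interface round out the toolkit.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
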
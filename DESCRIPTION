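Package: shouldersim
Title: Quasi-Static Musculoskeletal Simulation of Natural and Prosthetic Shoulders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A quasi-static rigid-body musculoskeletal simulator for the human
    shoulder, built to compare a natural gleno-humeral joint against a reverse
    shoulder prosthesis and a dual-bearing (glenoid-sparing, dual centre of
    rotation) shoulder prosthesis. Provides forward kinematics over
    fixed/hinge/gimbal/ball joint chains, Hill-type muscle force elements with
    sphere and ellipsoid obstacle wrapping, tendon-excursion moment arms,
    static-optimization resolution of muscle redundancy (minimum sum of squared
    activations, convex QP), gleno-humeral joint reaction forces, synthetic
    marker-capture motion generation with marker-based inverse kinematics and
    quasi-static time stretching, a Coulomb friction-moment bound for the
    prosthetic bearings, and table-level aggregation of peak muscle forces,
    activations and joint reaction forces with percent changes relative to the
    natural shoulder.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
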
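Package: vasotone
Title: Active Stress Models of Vascular Smooth Muscle Contraction in Arteries
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Constitutive modelling of vascular smooth muscle cell (VSMC)
    active contraction in incompressible thick- and thin-walled arterial
    cylinders. Implements six active circumferential stress formulations
    (constant Cauchy, constant 1st and 2nd Piola-Kirchhoff, Rachev-Hayashi,
    Zulliger, and Franchini models) with closed-form active load-bearing
    pressure terms, analytic limit-point stability conditions, a four-fibre
    family passive wall model, pressure-diameter curve simulation with
    instability-region detection and multi-root inversion, a thin-wall
    approximation for radius-to-thickness data, and nonlinear least-squares
    parameter estimation from sparse (single contraction point) or dense
    (paired relaxed/contracted pressure-diameter curves) data. Includes a
    deterministic synthetic-data generator emulating mouse thoracic aorta
    and canine artery contraction protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
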
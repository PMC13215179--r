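Package: tracerflow
Title: Physics-Informed Velocimetry from Dynamic Tracer Imaging
Version: 0.1.0
Authors@R: person("tracerflow", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reconstructs steady three-dimensional velocity, pressure, and
    permeability fields from time-resolved tracer-concentration volumes such
    as dynamic contrast-enhanced MRI of the glymphatic system. Couples a
    Darcy porous-media flow model with advection-diffusion tracer transport
    through a staged, physics-informed neural-field optimization with
    residual-based attention weighting. Includes a finite-volume forward
    simulator for ground-truthed synthetic cases, a preprocessing chain
    (signal enhancement ratio, exclusion masks, front-tracking velocity
    priors, early-arrival permeability priors), nondimensionalization,
    evaluation metrics, and ensemble-based uncertainty quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
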
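Package: stimfield
Title: Layered Volume-Conductor Fields and Nerve Activation for Surface
    Electrical Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-step modelling of transcutaneous functional electrical
    stimulation of the thigh. A quasistatic anisotropic volume-conductor
    solver computes the extracellular potential produced by a surface
    electrode pair over layered limb models (parallel slab, concentric
    cylinder, or synthetically perturbed pseudo-anatomy with blood-vessel
    and nerve-trunk inclusions); a McNeal compartment cable with CRRSS
    nodal kinetics then converts the potential profile along a straight
    myelinated fiber into an activation threshold by bisection on the
    stimulus amplitude. Sweep and comparison tooling reproduces
    model-representation studies: threshold tables over electrode size,
    interelectrode distance, fiber diameter, stimulation site and nerve
    depth, activation-error tables against a reference model,
    cross-correlation of threshold curves, and projection-based fat/bone
    geometry metrics with matching geometry adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    tibble,
    dplyr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
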
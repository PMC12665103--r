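Package: organflux
Title: Compartmental Transport and Glucose-Insulin Dynamics for a
    Convective Multi-Organoid Device
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reduced-order simulator of a recirculating two-chamber
    multi-organoid culture device: compartmental advection-diffusion
    transport of glucose and FITC-dextran tracers across a porous PTFE
    membrane, closed-form hydraulic quantities (wall shear stress in a
    rectangular channel, Darcy velocity, circulation time, membrane
    conductance), apparent-permeability estimation from donor/receiver
    assays, least-squares calibration of unprinted geometric parameters,
    and a minimal glucose-insulin feedback model reproducing in vitro
    glucose tolerance test and glucose-stimulated insulin secretion
    read-outs under control, palmitate, and palmitate+metformin
    conditions. Includes generators for synthetic tracer and glucose
    tolerance assays with multiplicative measurement noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
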
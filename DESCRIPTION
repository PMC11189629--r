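Package: elongrod
Title: Morphoelastic Rod Model of C. elegans Embryonic Elongation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the two-phase elongation of the
    Caenorhabditis elegans embryo as an actively contracting layered
    elastic cylinder. The package implements the early actomyosin-driven
    pre-strain model of a three-layer cylinder (compressible core,
    incompressible epidermis and contractile actin ring), a myosin
    recruitment ODE with parameter fitting, the asymptotic reduction of
    the active cylinder to an extensible rod (extension, bending and
    torsion stiffnesses and activation-induced intrinsic strains), a
    cyclic muscle-contraction simulator that converts per-cycle
    bending/torsion energy into axial elongation including mutant
    scenarios, and closed-form estimates of the rotation torques and
    viscous dissipation of the embryo inside the eggshell. Synthetic
    data generators and ggplot2 visualisations are included so the full
    analysis pipeline is testable without external data.
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
    pracma,
    purrr,
    rlang,
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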
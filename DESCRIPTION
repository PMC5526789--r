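Package: smcrod
Title: Cross-Link-Guided Modeling of SMC Coiled-Coil Rod Dimers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for turning in-vivo cysteine cross-linking screens of SMC
    (Structural Maintenance of Chromosomes) proteins into three-dimensional
    dimer models. Covers heptad-register-aware screen design, cross-linking
    efficiency tables and axial-residue calling, joining efficiencies with
    symmetry-mate Calpha distances in crystal structures, automated
    cross-link-restrained C2-symmetric rigid-body docking, composite
    full-length rod assembly from overlapping fragments, screw-axis
    decomposition of the rod-to-ATP-engaged head transition, coiled-coil
    bending toward ring models, and the small quantitative fits that
    accompany such screens (subunit-exchange kinetics, ChIP/input ratios).
    A synthetic-data generator produces idealized Crick-parameterized
    coiled-coil rods with planted C2 axes and simulated efficiencies so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
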
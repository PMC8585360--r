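Package: boneplough
Title: Mechanistic Force Models for Ploughing Cortical Bone with a
    Single-Point Diamond Tool
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Models and calibration tools for the forces generated when a
    conical single-point diamond tool ploughs microgrooves into cortical
    bone.  Provides closed-form conical-contact normal-force laws, an
    empirical power law linking normal force to indented volume, an
    orientation-dependent (anisotropic) ploughing-coefficient model built
    on the osteon cutting angle, robust Hampel filtering and steady-state
    summarisation of dynamometer force traces, least-squares calibration
    of both models with regression diagnostics, and a seeded synthetic
    experiment generator emulating full-factorial cutting trials so the
    whole pipeline is testable without laboratory data.
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
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
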
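Package: otosim
Title: Scriptable Simulation of Middle-Ear Microsurgery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A scriptable, testable simulator of middle-ear microsurgery on
    procedurally generated anatomy. Provides a small-deformation (optionally
    corotational) finite-element model of the ossicular chain and tympanic
    membrane with Rayleigh damping and implicit backward-Euler time stepping,
    signed-distance-field bone drilling by constructive-solid-geometry
    subtraction with marching-tetrahedra surface extraction, unilateral
    tool/prosthesis contact resolved by projected Gauss-Seidel, and scripted
    surgical procedures (stapedotomy, single- and two-arm stapedioplasty) with
    procedure-quality metrics: drilled volume, distance to target, per-axis
    incus displacement, contact-force traces, damage flags, and a composite
    quality score built from placement error, a force functional, visual
    obstruction time, and the ossicular-chain transfer function.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
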
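Package: spinpair
Title: Phenomenological Models for Exchange and Dipolar Coupling in
    Nitroxide Radical Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the phenomenological modelling of interacting
    pairs of nitroxide (TEMPO-type) spin probes: the Yamaguchi
    broken-symmetry estimate of the Heisenberg exchange coupling J,
    magneto-structural exponential laws J(r) with a cos^2(alpha) angular
    dependence and their ferro/antiferromagnetic decomposition,
    point-dipole models (two-point and four-point) of the zero-field
    splitting tensor with D and E extraction and lobe-offset fitting,
    counterpoise (BSSE) interaction-energy arithmetic with
    dispersion-shift bookkeeping, and plane-wave basis-cutoff
    extrapolation via component-wise exponential fits. Includes
    parametric geometry builders for idealized colinear radical-pair
    arrangements, synthetic-data generators for every stage, and a
    registry of published reference tables packaged as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
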
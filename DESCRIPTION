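Package: turbtank
Title: Turbulent Flow Analysis for Reciprocating-Impeller Bioreactors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale computational fluid dynamics toolkit for cell-culture
    bioreactors stirred by vertically reciprocating disc impellers. Provides
    parametric tank geometry and geometric-similarity scaling, axisymmetric
    structured-grid generation, a steady incompressible finite-volume RANS
    solver (SIMPLE pressure-velocity coupling, realizable k-epsilon closure,
    equilibrium wall functions) run at quasi-steady impeller positions,
    post-processing of turbulence metrics (turbulent viscosity, strain rate,
    shear stress, vorticity, Kolmogorov scale), quantification of the
    defective (quiescent) turbulent flow volume across impeller-position
    snapshots, and a speed-matching procedure that selects the motion speed
    reproducing a reference tank's turbulent energy and shear stress at a
    different scale. Includes analytic synthetic-field generators and a
    method-of-manufactured-solutions verification harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
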
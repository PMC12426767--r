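Package: wssbench
Title: Finite-Element Evaluation of Wall Shear Stress for Incompressible Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solves stationary Stokes and steady-state Navier-Stokes problems
    with mixed finite elements (stabilized equal-order P1/P1 and Taylor-Hood
    P2/P1) on simplicial meshes, and recovers wall shear stress (WSS) either by
    L2 projection of the tangential traction onto continuous or discontinuous
    boundary spaces, or by a variationally consistent boundary-flux evaluation.
    Includes structured mesh generators for the unit square and for tetrahedral
    cylinders with optional near-wall boundary layers, analytic benchmark
    solutions, mesh-convergence studies with fitted rates, and hemodynamic
    indicators (dome WSS extrema, averages, and low shear area) for tagged
    vascular meshes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    xml2,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
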
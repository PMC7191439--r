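Package: airflowsim
Title: Axisymmetric RANS Simulation of Stenotic Airway Flow and Virtual
    Surgical Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale computational pipeline for evaluating staged surgical
    correction of a trachea with multiple stenotic segments. Provides parametric
    axisymmetric airway geometries with virtual stenosis application and
    correction, wall-clustered structured finite-volume meshing, a steady
    incompressible Reynolds-averaged Navier-Stokes solver with the Wilcox
    k-omega closure (SIMPLE pressure-velocity coupling, second-order upwind
    convection, Rhie-Chow momentum interpolation), aerodynamic read-outs
    (pressure drop, wall shear stress, energy-loss rate, Reynolds number), and
    a lumped bronchial resistance network for left/right airflow distribution.
    Includes scenario generators for a patient-like two-stenosis case and its
    four correction variants, validation fixtures with analytic oracles, and a
    grid-sensitivity driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
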
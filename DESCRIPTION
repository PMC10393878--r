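Package: vffrsim
Title: Virtual Fractional Flow Reserve from Steady Coronary CFD at
    Controllable Mesh Fidelity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for computing virtual fractional flow
    reserve (vFFR) in stenosed coronary vessels. Generates parametric
    stenosed-vessel lumens with STL import/export, builds body-fitted
    structured hexahedral (butterfly) meshes whose cell count is driven by
    a 1-100 percent fidelity slider, solves steady incompressible
    Navier-Stokes flow with a SIMPLE-type pressure-based finite-volume
    scheme, characterises each lesion by a two-point quadratic
    pressure-flow curve, and couples it to a lumped distal microvascular
    resistance to obtain vFFR by closed form and by pseudo-transient
    iteration. Includes a mesh-fidelity benchmarking harness (accuracy
    metric, Bland-Altman limits of agreement, exact Wilcoxon signed-rank
    with Hodges-Lehmann confidence intervals, ANCOVA slope comparison,
    threshold concordance) and an energy/monetary cost model for
    simulation campaigns.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
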
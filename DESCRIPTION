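Package: aortohemo
Title: Windkessel-Coupled Aortic Hemodynamics Simulation and Method-Agreement Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Image-free computational pipeline for aortic hemodynamics in
    congenital heart disease. Builds parametric synthetic aortas (arch,
    brachiocephalic/carotid/subclavian branches, descending aorta with an
    aortic-isthmus region), voxelizes them into labeled flow domains, and
    solves the incompressible Newtonian Navier-Stokes equations on a
    staggered Cartesian grid with pulsatile inlet flow and three-element
    Windkessel (lumped-parameter) outlet boundary conditions. Extracts peak
    systolic velocity, peak systolic pressure and wall shear stress, computes
    localized normalized helicity and streamlines, and implements the
    method-agreement statistics (Bland-Altman limits of agreement, linear
    fitting, normality/variance-gated paired tests) used to validate
    simulated hemodynamics against echocardiographic and catheter
    measurements. A seeded virtual-patient cohort generator reproduces the
    statistical structure of a 25-infant reference cohort so the full
    pipeline runs end to end without clinical data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml,
    car,
    nortest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
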
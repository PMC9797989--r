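Package: vimflow
Title: Intraventricular Hemodynamics After Transcatheter Mitral Valve
    Replacement in Calcified Annuli
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates left-ventricular blood flow after transcatheter
    mitral valve replacement in mitral annulus calcification and derives
    the haemodynamic risk metrics used in pre-procedural assessment.
    Provides a synthetic-anatomy generator for idealized moving-wall
    ventricles with an embedded bioprosthetic frame, B-spline free-form
    deformation wall tracking with Hausdorff validation, three-dimensional
    neo-LVOT area measurement against a posed cylindrical device, a
    two-dimensional immersed-boundary incompressible Navier-Stokes solver
    with a co-advected flow-age scalar, and reporting of LVOT pressure
    gradients, wall shear stress, oscillatory shear index, blood residence
    time and platelet-activation exposure checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    mgcv,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
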
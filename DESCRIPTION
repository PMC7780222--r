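Package: virtopop
Title: Virtual Tumor Populations from Reaction-Diffusion Models and Emission Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates population- and patient-specific virtual tumor
    populations by coupling a Fisher-KPP reaction-diffusion growth model with
    spatially heterogeneous lumpy random-field coefficients to a Poisson model
    for binned-mode emission computed tomography (ECT) data. Provides the
    lumpy-field object model (sampling, synthesis, parameter packing), a
    conservative finite-difference / adaptive Runge-Kutta solver for the
    growth equation, a Gaussian-blur continuous-to-discrete imaging operator,
    maximum-likelihood reconstruction (MLEM for linear lump bases,
    box-constrained quasi-Newton for nonlinear lump models), Fisher
    information analysis, Metropolis-Hastings posterior sampling over lump
    parameters, virtual-population biomarker prediction (tumor burden,
    integrated log-kill), and Monte-Carlo marginal-likelihood calibration of
    population hyperparameters from image databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
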
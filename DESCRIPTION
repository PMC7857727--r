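Package: ringfit
Title: Rigid-Body SAXS Modelling of Cyclic Multi-Domain Oligomers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Model-independent and model-based analysis of small-angle X-ray
    scattering (SAXS) data from ring-shaped multi-domain protein oligomers
    such as properdin. Provides reading, logarithmic rebinning and Guinier
    analysis of 1D profiles; regularized indirect Fourier transformation to
    the pair distance distribution p(r) with automatic D_max selection and
    peak detection; a Debye-formula bead-model intensity calculator; restrained
    rigid-body refinement of C_n symmetric assemblies by simulated annealing;
    principal-axis shape metrics including the binding-site orientation angle
    alpha; Bayesian maximum entropy (BME) ensemble reweighting; and a
    synthetic "eye + arm" oligomer generator so the whole pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
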
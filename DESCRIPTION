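Package: nanovasc
Title: Tumor-Induced Vascular Network Growth and Nanoparticle Vascular Adhesion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale two-dimensional simulator of vascularized tumor
    growth and the vascular deposition of systemically injected
    nanoparticles. Couples a continuum tumor model (Darcy tissue mechanics,
    viable/hypoxic/necrotic regions, quasi-steady oxygen and angiogenic
    factor transport) with stochastic lattice angiogenesis, microvascular
    network hemodynamics (Poiseuille flow, Fahraeus-Lindqvist viscosity,
    hematocrit partitioning, Pries-type structural radius adaptation), and
    an advective nanoparticle transport and shear-dependent wall adhesion
    model on the resulting vessel graph. Reports tumor radius, per-class
    blood area fractions, mean flow and wall shear, and adhered particle
    fraction per tumor area over 24 days post tumor inception.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    parallel,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
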
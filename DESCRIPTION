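Package: chargereg
Title: Charge-Regulated Poisson-Boltzmann Modelling of Nanoparticle
    Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the pH-dependent surface charge of mesoporous silica
    nanoparticles (bare and amino-functionalized) with a charge-regulation
    model of silanol and amine protonation equilibria coupled to a
    one-dimensional modified Poisson-Boltzmann equation, optionally
    including Mahanty-Ninham ionic dispersion potentials. Predicts zeta
    potentials at a hydrodynamic slipping plane, locates isoelectric
    points, and fits charge-regulation parameters (site pK values and
    surface densities) to zeta-pH titration data by multi-start nonlinear
    least squares. Also quantifies adsorbed mass from quartz crystal
    microbalance with dissipation (QCM-D) traces via the Sauerbrey
    equation and grafting density from thermogravimetric mass loss, and
    generates seeded synthetic titrations and QCM traces for validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    lhs,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
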
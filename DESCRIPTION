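Package: spindyn
Title: NMR Spin Relaxation Dynamics and RNA-Binding Analysis for
    Double-Stranded RNA-Binding Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of backbone amide 15N spin relaxation and
    protein-RNA binding data for double-stranded RNA-binding domains
    (dsRBDs). Provides mono-exponential relaxation-rate fitting with
    duplicate-delay noise estimation and Monte-Carlo uncertainties,
    steady-state heteronuclear nOe calculation, constant-time CPMG
    effective transverse rates and dispersion assessment, extended
    Lipari-Szabo model-free analysis with isotropic or axially symmetric
    global diffusion, two-state Bloch-McConnell simulation and fitting of
    heteronuclear adiabatic relaxation dispersion (HARD) experiments with
    hyperbolic-secant (HSn) spin locks, NMR titration isotherm and
    single-site isothermal titration calorimetry (ITC) fitting, and a
    synthetic-data generator with embedded ground truth for end-to-end
    recovery studies. Includes a small RNA-duplex base-pairing utility.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
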
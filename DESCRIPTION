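Package: micropk
Title: Micro-Pharmacokinetics: Local Ligand Concentrations at Cell Membranes by FCS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification pipeline for micro-pharmacokinetic measurements of
    local ligand concentration near cell membranes by fluorescence correlation
    spectroscopy (FCS). Simulates photon-count fluctuation traces from 3D- and
    membrane-confined 2D-diffusing fluorophores sampled by a Gaussian confocal
    volume; computes multi-tau autocorrelation functions; fits one-component 3D
    and mixed 3D+2D diffusion models; calibrates the detection volume from a
    reference dye; converts particle numbers to molar concentrations, including
    brightness-corrected membrane-phase estimates; analyses TR-FRET equilibrium
    and kinetic binding data (Kd, kon, koff); aggregates distance- and
    time-resolved concentration gradients with the associated statistics; and
    computes the "true affinity" correction that substitutes the measured local
    ligand concentration for the bulk concentration.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    car,
    emmeans,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
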
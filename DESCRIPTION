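Package: atrialab
Title: Pulmonary-Vein Electrophysiology, Fibrosis and Arrhythmia Inducibility on Idealized Atrial Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale in-silico laboratory for studying how pulmonary-vein (PV)
    electrophysiology, fiber architecture and fibrosis shape atrial-fibrillation
    inducibility, driver location and the outcome of pulmonary-vein isolation.
    Provides an idealized left-atrial surface-mesh generator with PV sleeves,
    the Courtemanche-Ramirez-Nattel human atrial ionic model with persistent-AF
    remodelling plus a fast two-variable surrogate, an anisotropic monodomain
    reaction-diffusion solver on triangulated surfaces with interstitial-fibrosis
    edge decoupling, clinical-style extrastimulus inducibility batteries,
    in-silico pulmonary-vein isolation, and phase-singularity detection,
    tracking and density mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
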
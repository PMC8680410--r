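Package: oxybeads
Title: Hybrid Continuum-Agent Simulation of Self-Oxygenating Implant
    Vascularization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the post-implantation fate of engineered tissues that
    carry oxygen-generating micromaterials (calcium peroxide, CPO, or
    PCL-encapsulated hydrophobic oxygen generators, HOGs). A tissue-level
    taxis-diffusion-reaction model of oxygen, VEGF, progenitor cells,
    fibroblasts and fibrous matrix is coupled to a discrete endothelial-cell
    model of sprouting angiogenesis with Dll4-Notch lateral inhibition.
    Beads follow an oxygen-gated, exponentially decaying release law and are
    placed randomly at a prescribed area fraction. The package provides
    scenario configuration and validation, release-parameter estimation from
    release curves, synthetic fixtures, implant metrics (anoxic fraction,
    VEGF load, vascular penetration depth), condition sweeps across bead
    types and fractions, and bench-assay calculators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    igraph,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'bead-release.R'
    'bench.R'
    'continuum.R'
    'vascular.R'
    'experiments.R'
    'io.R'
    'model-config.R'
    'synthetic.R'
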
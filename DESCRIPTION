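Package: hmsm
Title: Hybrid Multi-Scale Simulation of Castration-Resistant Prostate Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A 3D hybrid multi-scale model of prostate tumor growth and
    castration resistance in an immune microenvironment. Couples a lattice
    agent-based model of tumor, macrophage, T-cell and endothelial agents
    with reaction-diffusion cytokine fields, a two-compartment androgen
    level, tumor-induced angiogenesis, a lymph-node compartment with
    programmed T-cell activation, and an intracellular ODE model of
    WNT5A/EGF-driven androgen-independent androgen-receptor signaling fitted
    by a genetic algorithm. Supports in-silico castration and combination
    therapy experiments (anti-WNT5A, CSF1R inhibition, IL-2 neutralization,
    EGFR inhibition), replicate orchestration, fold-change summaries and
    parameter sensitivity scans.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    deSolve,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
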
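Package: mfdyn
Title: Model-Free Analysis of Backbone 15N Relaxation and NMR Ensemble
    Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Lipari-Szabo model-free analysis of backbone 15N relaxation
    data (R1, R2, heteronuclear NOE) for small proteins, as applied to
    disulfide-stabilized three-finger (Ly-6/uPAR) domains.  Provides the
    forward relaxation model (dipolar + chemical shift anisotropy +
    conformational exchange) for isotropic and axially symmetric rotational
    diffusion, monoexponential intensity-decay fitting, global diffusion
    tensor estimation, per-residue model selection with Monte-Carlo
    uncertainties, threshold classification of ps-ns and us-ms motions,
    Cys-anchored region aggregation of order parameters, multi-model NMR
    ensemble superposition and disorder profiles, order-parameter
    conformational entropy and Boltzmann affinity estimates, and a seeded
    synthetic-data generator so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    seqinr,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
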
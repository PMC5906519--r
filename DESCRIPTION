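Package: epduq
Title: Uncertainty Quantification for Epicardial Potential Distributions in
    Subendocardial Ischaemia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates ST-segment epicardial potential distributions (EPDs)
    over a slab of ventricular tissue in contact with a blood mass, using the
    passive bidomain equation with transmurally rotating anisotropic
    conductivity tensors and an analytic ischaemic transmembrane-potential
    source, and quantifies how fibre rotation, ischaemic depth, blood
    conductivity and the six bidomain conductivities shape ST
    depression/elevation.  Provides a vertex-centred finite-volume/Galerkin
    solver on graded hexahedral meshes, EPD feature extraction and pattern
    classification, stochastic collocation by Smolyak sparse grids of
    Clenshaw-Curtis points, Gaussian-process emulation with closed-form main
    effects and sensitivity indices, Mahalanobis-distance emulator validation,
    NIPALS partial-least-squares regression, Latin-hypercube designs, and
    study pipelines that run the scenario analyses end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    lhs,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
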
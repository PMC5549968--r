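Package: mwcfit
Title: Reliable Estimation of MWC Allosteric Parameters from Ligand
    Saturation Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for extracting the elementary parameters of the
    Monod-Wyman-Changeux (MWC) concerted allosteric model (the
    conformational equilibrium constant L and the state affinities K_R and
    K_T) from steady-state ligand saturation curves such as hemoglobin
    oxygen equilibrium data.  Implements an analytic three-equation-system
    solver operating on the identifiable compound parameters (L*K_R^4,
    L*c^4 and P50), global fitting of effector concentration curve
    families with shared affinities and per-curve apparent allosteric
    constants, the effector linkage fit for inhibitor affinities to the T
    and R conformations, Hill and compound-parameter single-curve fits,
    first-order error propagation, a synthetic saturation-curve simulator
    with known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
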
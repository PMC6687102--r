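Package: epgg
Title: Spatial Ecological Public Goods Games with Directed Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulator and stability-analysis toolkit for ecological public
    goods games with directed migration. Provides the well-mixed
    eco-evolutionary dynamics (mean payoffs, interior coexistence
    equilibrium, Hopf-bifurcation locator), linearized pattern-formation
    analysis (spatial Jacobian, dispersion relation, well-posedness and
    necessary conditions, dominant mode), a conservative finite-difference
    integrator for the selection-diffusion-taxis system on a periodic 2-D
    domain covering the four modes of directed migration (cooperator
    aggregation, defector hunting, cooperator flight, defector spreading),
    regime diagnostics (population and cooperation ratios, regime
    classification, pattern wavelength), and parameter-sweep orchestration.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    graphics,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
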
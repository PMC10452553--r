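Package: membranewalk
Title: Stochastic Simulation of Membrane-Protein Motion During Cell
    Communication
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the lateral motion of messenger proteins in a cell
    membrane during cell-to-cell communication. Provides exact and
    Monte-Carlo one-dimensional lattice random walks together with their
    continuum diffusion limit, Green's-function solutions of the free
    diffusion equation, a multiplicative-noise stochastic differential
    equation for protein position under an external force and a drag
    force integrated by the Euler-Maruyama scheme with strong-convergence
    diagnostics, and a dimensionless advection-diffusion equation with
    spatially dependent diffusivity solved by the method of lines.
    Includes seeded run manifests, tabular writers and a command-line
    driver for reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
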
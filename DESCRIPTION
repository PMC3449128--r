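Package: fbrstab
Title: Stability Analysis of a Reaction-Diffusion-Chemotaxis Model of
    Foreign Body Fibrotic Reactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a five-field kinetic model of the foreign body
    reaction around implanted devices (tissue debris, chemoattractant,
    fibroblasts, macrophages and extracellular matrix). Provides the
    closed-form interior (inflammatory) equilibrium and its existence
    region over macrophage phenotype fractions, closed-form eigenvalues
    of the linearized reaction system and of every spatial Fourier mode
    under homogeneous Neumann boundary conditions, energy-method
    (Lyapunov) sufficient stability conditions built on the Poincare
    inequality, a coefficient-level counter-example construction in
    which chemotaxis destabilizes an otherwise decaying mode, and a
    method-of-lines simulator for the full nonlinear and linearized
    systems on intervals and rectangles with growth-rate estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
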
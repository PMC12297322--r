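Package: nscfeedback
Title: Feedback-Regulated Neural Stem Cell Lineage Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nonlinear compartmental models of the adult neural stem cell
    lineage in the ventricular-subventricular zone, in which the activation
    rate of quiescent stem cells and the self-renewal fraction of active
    stem cells are Hill-type functions of lineage subpopulation sizes.
    Provides scenario simulation, steady-state and linear stability
    analysis including the self-renewal bifurcation, a quasi-steady-state
    signalling extension, weighted least-squares multistart parameter
    estimation with linearized covariance, AICc model selection with
    Akaike weights, adaptive Metropolis posterior sampling with randomized
    initial conditions, in silico chemotherapy (temozolomide) and
    interferon-receptor knockout perturbation experiments, and a generator
    of synthetic per-mouse longitudinal datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
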
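Package: il7rpkpd
Title: Quasi-Equilibrium TMDD and Dose-Response Modelling of an Anti-IL-7R-Alpha Antibody
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mechanistic pharmacokinetic/pharmacodynamic modelling of a
    humanized IgG1 monoclonal antibody directed against the interleukin-7
    receptor alpha chain (IL-7Ralpha), which circulates as a soluble protein
    and is expressed on T cells. Implements a two-compartment
    target-mediated drug disposition (TMDD) model with a quasi-equilibrium
    binding approximation for the two receptor forms, an indirect-response
    Emax dose-response model for effector-memory and regulatory T-cell
    counts, population simulation with log-normal inter-individual
    variability and additive/proportional residual error, synthetic
    multiple-ascending-dose trial generation, prediction-corrected visual
    predictive checks, Laplace-type population estimation of the
    dose-response model with nonparametric bootstrap uncertainty, and
    per-subject empirical-Bayes PK estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
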
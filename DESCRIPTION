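Package: transpkpd
Title: Translational PK-PD Modelling and First-in-Human Dose Selection
    for a Bispecific HER2xHER3 Antibody
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the translational pharmacokinetic-pharmacodynamic
    modelling chain used to select first-in-human doses for a bispecific
    HER2xHER3 IgG1 antibody: a two-compartment disposition model with
    parallel linear and Michaelis-Menten (target-mediated) clearance,
    allometric scaling of parameters between cynomolgus monkey, human and
    mouse, a JIMT-1 xenograft tumor-growth-inhibition model driven by the
    scaled mouse pharmacokinetics, and the dose-selection calculus built on
    them (AUC-based safety margins against the monkey NOAEL exposure,
    receptor-occupancy predictions, a Km sensitivity sweep, and AUC-matched
    cross-species dose translation).  Includes nonlinear mixed-effects
    simulation (lognormal between-subject variability, combined residual
    error, below-quantification-limit handling), maximum-likelihood
    estimation by Laplace or first-order approximation of the marginal
    likelihood, and generators for study-shaped synthetic datasets so the
    whole chain is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
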
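Package: virimmune
Title: Multistability and Recovery Dynamics of a Virus-Immune Feedback Network
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a six-compartment ordinary-differential-equation model
    of within-host virus-immune interaction (viral load, innate immunity,
    cellular immunity, humoral immunity, immune suppression, and IL-6) with
    Hill-function cross-regulation and a piecewise-constant exogenous viral
    input. Provides stiff simulation of exposure scenarios, a multistart
    Newton census of equilibria with eigenvalue stability classification,
    one- and two-parameter bifurcation scans, basin-of-attraction mapping
    over initial-condition grids, infectious- and illness-duration indicators
    with multi-parameter perturbation sensitivity, and exhaustive subsystem
    enumeration for bistability frequency analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
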
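Package: ligandkin
Title: Receptor-Ligand Binding Kinetics and Equilibrium Pharmacology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form two-ligand competition binding kinetics
    (Motulsky-Mahan) and a rapid-competitor-dissociation limit for
    fast-off compounds, with nonlinear least-squares fitting of
    time-course tracer traces, global parameter sharing across competitor
    concentrations, and partial F-test selection between nested kinetic
    models. Also provides equilibrium pharmacology (three-parameter
    logistic dose-response fitting, Schild regression pA2/pKB, saturation
    binding, one-site competition with Cheng-Prusoff conversion) and
    substrate-depletion pharmacokinetics (first-order half-life, intrinsic
    clearance). Includes synthetic plate generators with known ground
    truth, CSV/JSON input-output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    deSolve,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
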
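Package: raftfilm
Title: Langmuir Monolayer Thermodynamics and Electrochemical Analysis of
    Lipid-Raft Model Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for biomimetic lipid-raft membranes built from
    DOPC, cholesterol and sphingomyelin. Extracts descriptors from Langmuir
    surface pressure-area isotherms (reciprocal compression modulus, phase
    assignment, limiting areas, kink and collapse pressures, film stability),
    computes ideal-mixing references and excess thermodynamic quantities
    (excess area, excess Gibbs energy, percent condensation) for ternary
    films, converts AC-voltammetric responses of electrode-supported bilayers
    into differential capacitance, charge density, potential of zero free
    charge and surface coverage, and fits electrochemical impedance spectra
    to a constant-phase-element equivalent circuit by complex nonlinear least
    squares. Includes seeded synthetic-data generators that emulate the four
    DOPC:Chol:SM compositions so every stage of the pipeline can be verified
    end to end without laboratory data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
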
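Package: carbakin
Title: Covalent Glycosidase Inhibition Kinetics and Ring-Puckering Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing mechanism-based covalent inhibition of
    glycoside hydrolases by carbasugars: closed-form steady-state theory of the
    covalent-inhibition cycle (kcat, Km, kinact, Ki and derived half-lives and
    fold ratios), mass-action ODE simulation of turnover, sequential-mixing
    stopped-flow and dilution assays, nonlinear least-squares parameter
    inference with linear/hyperbolic model selection, synthetic assay-data
    generation, Cremer-Pople and Hill-Reilly ring-puckering descriptors with
    IUPAC conformer classification for six-membered rings, and PDB/mmCIF
    structure utilities (superposition, atom displacements, hydrogen-bond
    contacts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
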
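Package: qmredox
Title: QM Cluster Models and Thermodynamic-Cycle Redox Potentials for
    Metalloenzyme Active Sites
Version: 0.1.0
Authors@R:
    person("qmredox", "maintainers", email = "qmredox@example.org",
           role = c("aut", "cre"))
Description: Tools for building truncated, hydrogen-capped, partially frozen
    quantum-mechanical (QM) cluster models of metalloenzyme active sites from
    protein structures in PDB format, and for evaluating one-electron
    reduction potentials through the standard thermodynamic cycle
    (gas-phase Gibbs free energy change plus differential solvation free
    energy, converted to a potential and referenced to the standard hydrogen
    electrode). Includes a PDB/XYZ structure layer with residue selection,
    metal-site detection and coordination-shell analysis, side-chain plus
    alpha-carbon carving with link-atom capping and frozen-atom bookkeeping,
    per-redox-state charge and spin-multiplicity assignment, Gaussian-style
    input-deck generation and output-log parsing, energy-table ingestion,
    metal-ligand distance and Kabsch-superposition RMSD analysis, synthetic
    type-1 copper site fixtures for end-to-end testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
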
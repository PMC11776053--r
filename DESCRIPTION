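Package: alchemap
Title: Perturbation Map Planning for Relative Free-Energy Calculations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Plans alchemical perturbation networks for relative binding
    free-energy (RBFE/FEP) campaigns. Between a pair of structurally
    distant ligands the package exhaustively enumerates chemically small
    intermediate compounds by graph editing toward the maximum common
    substructure (computed with tolerance for atom-type mismatches),
    scores candidate transformations with an exponential link score,
    selects the optimal intermediate path under score and distance
    thresholds, and assembles a cycle-closed perturbation map in which
    every optimal link is protected by a small thermodynamic cycle. A
    congeneric-series mode injects intermediate paths into a Lomap-style
    map until no planned transformation between series members falls
    below a link-score threshold. Molecule handling (SMILES/SDF parsing,
    canonicalization) is delegated to Open Babel via ChemmineOB; maps are
    exported as GraphML and CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
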
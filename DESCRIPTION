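Package: redoxmap
Title: Electrostatic Interaction Mapping and Redox Analysis for c-Type Cytochrome Partner Specificity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing redox-partner specificity between small
    c-type cytochromes and multiheme enzymes such as hydroxylamine oxidase.
    Implements rigid-body Metropolis Monte Carlo interaction mapping of a
    ligand protein in the screened-Coulomb electrostatic field of a receptor,
    heme redox-state charge models, interaction-surface extraction from pose
    ensembles, spectroelectrochemical Nernst fitting of titration curves, and
    Michaelis-Menten analysis of hydroxylamine-oxidation kinetics. Includes
    synthetic-structure and synthetic-data generators so the full pipeline is
    testable without external coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    withr
Config/testthat/edition: 3
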
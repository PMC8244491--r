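Package: olfscreen
Title: Biophysical Template Selection and Atomic-Property-Field Screening
    for Olfactory Receptors
Version: 0.1.0
Authors@R:
    person("olfscreen", "maintainers", email = "maintainers@olfscreen.org",
           role = c("aut", "cre"))
Description: Toolkit for ligand discovery against olfactory receptors and
    other class A GPCRs lacking experimental structures.  Implements a
    biophysical template-selection cascade (Eisenberg moving-window
    hydrophobicity correspondence between transmembrane helices, global
    sequence identity and query coverage, ligand-profile comparison by
    fingerprint Tanimoto similarity, and orthosteric-pocket scoring with a
    GPCR-specific substitution matrix), a ligand-based first-stage screen
    built on seven-channel atomic property field (APF) pharmacophores with
    rigid-body superposition, and the MM-GBSA component-aggregation
    arithmetic used to rank final receptor-ligand complexes.  Includes
    synthetic-data generators (transmembrane receptors with controlled
    hydrophobicity; active/decoy small-molecule libraries) so every stage is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python' on
    PATH (used for molecular perception, fingerprints and 3D embedding).
Config/testthat/edition: 3
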
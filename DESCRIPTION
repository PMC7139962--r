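Package: ribostate
Title: Implicit-Solvent Binding Free Energies and Conformational States of
    Riboswitch Aptamers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: End-point molecular mechanics / generalized Born surface area
    (MM-GB/SA) analysis of RNA aptamer-ligand snapshot ensembles: Coulomb,
    Lennard-Jones, OBC generalized Born polar solvation and Shrake-Rupley
    surface-area nonpolar terms with per-nucleotide free energy decomposition,
    harmonic normal-mode vibrational entropy, trajectory geometry (RMSD, RMSF,
    hydrogen-bond occupancy, mass-center distances), open/middle/closed
    conformational-state classification with threshold derivation, and
    synthetic-data generators with planted ground truth for validating every
    stage. Developed around the purine (adenine/guanine) riboswitch aptamer
    and its published binding and state tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'constants.R'
    'data.R'
    'selection.R'
    'molsys.R'
    'energy.R'
    'geometry.R'
    'gradients.R'
    'nma.R'
    'synthetic.R'
    'states.R'
    'pipeline.R'
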
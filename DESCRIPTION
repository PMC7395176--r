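Package: RectiDock
Title: Recurrence-Rectified Docking-Score Triage for Interface Stabilizers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: In-silico triage of small-molecule stabilizers of
    protein-protein interfaces from multi-run docking ensembles.
    Reads AutoDock DLG, multi-model PDBQT and generic pose tables,
    partitions poses into conformational clusters by greedy
    energy-sorted leader clustering on heavy-atom RMSD, converts
    binding free energies to dissociation constants, and rectifies the
    calculated Kd by an anchored sigmoidal multiplication factor on
    best-pose recurrence to produce a normalized Kd ranking.  Also
    provides Henderson-Hasselbalch protonation-state speciation and
    Lipinski bioavailability checks for druggability triage, LDH
    percent-cytotoxicity and viability-ratio plate statistics with a
    four-parameter log-logistic LD50 fit, and seeded synthetic-data
    generators (pose ensembles, compound panels, assay plates) with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
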
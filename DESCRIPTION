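Package: atroscreen
Title: Dual-Target Virtual-Screening Analytics with MM-PBSA Decomposition
    and Axial-Chirality Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis layer for ensemble-docking virtual screens against the
    PI3K-alpha/mTOR dual-target axis: cross-docking success matrices and
    minimal receptor-ensemble selection, pose and trajectory RMSD/RMSF
    metrics, single-trajectory MM-PBSA binding-energy bookkeeping with
    per-residue decomposition, radial cumulative interaction-energy profiles
    with a convergence-radius criterion, axial-chirality (Ra/Sa)
    enantiopreference classification for atropisomeric biflavonoids, and
    screening triage (top-decile selection, dual-inhibition profiling,
    Lipinski rule-of-five filters). Includes seeded synthetic-data
    generators with planted ground truth for every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    ChemmineR,
    ChemmineOB
Config/testthat/edition: 3
RoxygenNote: 7.3.3
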
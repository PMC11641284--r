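Package: mutadyn
Title: Comparative Structural Dynamics of Wild-Type and Point-Mutant Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing pipeline for comparing the structural dynamics of a
    wild-type protein against point mutants from multi-model PDB trajectories:
    least-squares (Kabsch) superposition with per-frame RMSD and per-residue
    Calpha RMSF, equilibration windowing, focal-residue centre-of-geometry
    distance patterns, geometric hydrogen-bond detection with frame occupancies
    and conventional-bond classification, Eisenberg-scale hydrophobicity sums,
    pairwise global-alignment sequence identity, and a per-mutant effect
    classification (conformation change and hydrogen-bond occupancy change per
    binding region). Includes a seeded synthetic-trajectory generator with
    planted fluctuation amplitudes, rigid loop displacements and hydrogen-bond
    occupancies so that every stage is testable without molecular-dynamics
    output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
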
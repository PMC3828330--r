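Package: actdyn
Title: Trajectory Analysis of Protein Domain Dynamics
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for molecular dynamics trajectories of small
    protein domains, built around the regulatory ACT domain of phenylalanine
    hydroxylase. Provides multi-model PDB input/output, least-squares
    (Kabsch) superposition with RMSD/RMSF, essential dynamics (principal
    component analysis of C-alpha fluctuations) per trajectory and combined
    across systems, dynamic cross-correlation matrices and correlation webs,
    functional mode analysis of the collective motion maximally correlated
    with a scalar observable, water density maps with hydration-site
    detection and per-atom hydration scores, Shrake-Rupley solvent
    accessible surface area, geometric hydrogen-bond detection, a reduced
    secondary-structure classifier, windowed minimum side-chain distance
    matrices, pairwise global sequence alignment with atom-map construction,
    and a synthetic-trajectory generator with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
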
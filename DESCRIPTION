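Package: trajan
Title: Analysis of Protein Molecular Dynamics Trajectories in Multi-Model PDB Format
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Toolkit for analysing protein molecular dynamics trajectories
    stored as multi-model PDB files: least-squares (Kabsch) rigid superposition
    with per-frame RMSD and per-residue RMSF, Kabsch-Sander hydrogen-bond based
    helix/coil assignment, residue contact occupancy maps, salt-bridge distance
    and denticity classification, named-atom hydrogen-bond persistence,
    rigid-domain rotation/translation mapping after core alignment, and
    Gaussian-mixture decomposition of inter-residue distance populations.
    Includes a seeded generator of synthetic two-chain trajectories with
    programmable ground truth for validation, and a configuration-driven
    pipeline that produces a complete, reproducible report bundle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    bio3d,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
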
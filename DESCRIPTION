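Package: pocketqsar
Title: Physically-Based 3D-QSAR by Virtual Binding-Pocket Induction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Induces a virtual binding pocket ("pocketmol") of typed
    molecular probes from 3D ligand poses and binding activities by
    deterministic greedy optimization of a multi-term objective, then
    predicts activities and bound poses of new ligands by flexible
    fitting against the induced pocket.  Predictions are reported as
    RMSD-linked pose families ranked by Boltzmann-derived probabilities,
    with probabilistically normalized confidence, novelty and
    excluded-volume metrics defining an applicability domain.  Includes
    an exploration-envelope penalty, substructure conformation and
    alignment constraints, rank-correlation model statistics with
    permutation significance, and a synthetic ground-truth pocket
    generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
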
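Package: helixgraft
Title: Epitope Grafting onto Helical Scaffolds with Conformational and
    Energetic Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing scaffold-grafted helical antigens and
    evaluating whether a grafted segment retains its native helical
    conformation.  Builds chimeric constructs by excising a scaffold loop
    and inserting a donor helix with flexible linkers sized from anchor
    geometry; assigns alpha-helical secondary structure per frame from
    Kabsch-Sander backbone hydrogen-bond energies; computes segment
    C-alpha RMSD time series with Kabsch superposition and replicate
    statistics; decomposes residue-pair nonbonded (Coulomb plus
    Lennard-Jones) interaction energies into banded matrices and ranks
    inter-helix contributors; and calls binder epitopes from differential
    hydrogen-deuterium exchange uptake tables.  Includes seed-deterministic
    synthetic generators (ideal helices, a toy graftable scaffold,
    Zimm-Bragg helix-coil fraying trajectories with latent ground truth,
    and HDX uptake curves with planted protection) so the whole pipeline
    is testable without external structures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
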
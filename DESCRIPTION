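Package: steps
Title: Structure-Aware Protein Self-Supervised Learning with Residue Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pretrains a residue-graph neural network on protein backbone
    structures with two self-supervised tasks: multi-class classification of
    pairwise C-alpha distance bins and regression of masked backbone dihedral
    angles (phi/psi). A pluggable protein sequence encoder is coupled to the
    graph model through a Jensen-Shannon mutual-information objective,
    optimized with a pseudo bi-level scheme in which the sequence encoder is
    perturbed for gradient computation but never persisted. Includes a
    synthetic-backbone generator (ideal helix, ideal strand, random coil) with
    analytically known geometry, a minimal PDB backbone reader/writer, a
    reverse-mode automatic-differentiation tape used for all training, and a
    finetuning harness for protein-level classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
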
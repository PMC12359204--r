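Package: lanthifold
Title: Lanthipeptide Conformer Ensembles from Ensemble-Averaged NOE Restraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Topology-aware modelling of lanthipeptides: parsing and validation
    of ring topologies (lanthionine and methyllanthionine thioether crosslinks,
    dehydrated residues), internal-coordinate conformer construction with
    cyclic-coordinate-descent ring closure, Ramachandran-style torsion tables
    for dehydroalanine and dehydrobutyrine, Monte-Carlo conformer sampling with
    a simplified score, r^-6 ensemble-averaged NOE distance restraints with
    Monte-Carlo selection of conformer ensembles, atropisomer classification
    and filtering, multi-model PDB input/output, and deterministic synthetic
    fixture generators for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
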
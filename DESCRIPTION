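Package: rnassess
Title: Assessment Metrics for RNA 3D Structure Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares predicted RNA three-dimensional models against a
    reference structure with the metric suite used in blind RNA structure
    prediction assessments: optimal-superposition RMSD, Interaction Network
    Fidelity (Watson-Crick, non-Watson-Crick and stacking categories),
    Deformation Index, per-residue anchored Deformation Profile matrices,
    torsion-space comparison by the Mean of Circular Quantities (global and
    local), and a steric clash score.  Includes a geometric base-pair and
    stacking annotator, PDB input/output for RNA, residue correspondence by
    index, number or sequence alignment, and a synthetic decoy generator
    (ideal A-form duplexes perturbed by coordinate noise, rigid domain
    motion, or bond rotation) so every metric is testable with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
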
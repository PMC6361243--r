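Package: pairsite
Title: Partner-Specific Prediction of Protein-Protein Interfaces from Residue Pair Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts partner-specific residue-residue contacts and binding-site
    residues for a pair of interacting proteins. Residues of both partners are
    encoded with sequence features (one-hot identity, PSSM/PSFM profile columns,
    entropy-based conservation) and structural features (secondary structure,
    relative solvent accessibility, half-sphere exposure, contact number,
    hydrophobicity), augmented with sequential sliding-window environments and
    Voronoi-neighborhood structural environments over the C-alpha Delaunay
    tessellation. Cross-chain residue pairs are scored by a two-step stacked
    gradient-boosted tree classifier; the second step consumes first-step scores
    and their structural pairwise environments. Pair scores are converted into
    per-residue binding-site scores by a rank-based scoring function with
    sequence-window smoothing and isotonic expected-precision calibration.
    Includes leave-one-out evaluation over complexes, a partner-specificity
    Mann-Whitney test, and a deterministic synthetic-complex generator so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    xgboost
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
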
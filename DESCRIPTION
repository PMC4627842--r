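Package: idpred
Title: Per-Residue Prediction of Intrinsic Protein Disorder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts intrinsically disordered residues in protein chains
    from sequence and profile information. Each residue is encoded by 56
    features (amino-acid identity, seven physicochemical properties,
    normalized PSSM log-odds, predicted secondary-structure probabilities,
    solvent accessibility, backbone torsion-angle fluctuations,
    profile-derived monogram/bigram conservation summaries and a terminal
    indicator), assembled over a sliding window and classified by a
    soft-margin RBF-kernel support vector machine with grid-searched
    hyperparameters and sigmoid-calibrated disorder probabilities.
    Includes a CASP-style evaluation suite (balanced accuracy, weighted
    score Sw, MCC, AUC with stratified bootstrap confidence intervals,
    content-level MAE), residue-level and sequence-level cross-validation,
    post-hoc composition and region diagnostics, and a seeded
    synthetic-data generator so the whole pipeline can be exercised
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    optparse,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    Biostrings,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
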
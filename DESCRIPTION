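Package: mutstab
Title: Structure-Based Prediction of Protein Stability Changes upon Missense Mutation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts changes in protein unfolding free energy (ddG, kcal/mol)
    induced by single missense mutations from a protein 3D structure, using a
    random-forest regression scoring function over ten evolutionary and
    structural features, trained on a symmetric dataset of forward and reverse
    mutations.  Includes a Shrake-Rupley solvent-accessibility engine with
    core/surface classification, a PSI-BLAST PSSM reader, dataset curation
    tools (reverse-mutation augmentation, conflict resolution, sequence-based
    protein clustering), five cross-validation protocols that keep
    forward/reverse pairs together, an anti-symmetry audit, ROC/MCC/AUC
    analysis with DeLong and Fisher-z comparisons, and a synthetic-fixture
    generator for fully offline testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    randomForest,
    pROC,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
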
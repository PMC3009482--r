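Package: phoskin
Title: Kinase-Specific Phosphorylation Site Prediction with Profile
    Alignment and Indirect-Relationship Noise Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts kinase-specific phosphorylation sites from protein
    sequence by combining a fixed-window BLOSUM62 peptide similarity with a
    gapped profile-profile alignment score, and re-ranks reference peptides
    with a noise-reducing classifier that exploits indirect similarity
    relationships among known phosphopeptides. Includes readers for FASTA,
    Phospho.ELM-style phosphosite tables and PSI-BLAST ASCII position
    specific scoring matrices, a seeded synthetic-data generator with
    planted sequence motifs, and a leave-one-out / k-fold cross-validation
    harness with accuracy, precision, recall and ROC reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
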
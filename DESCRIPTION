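Package: contactrank
Title: Two-Stage Residue-Residue Contact Prediction by Ranking Fusion
Version: 0.1.0
Authors@R: person("Contactrank", "Developers", role = c("aut", "cre"),
    email = "maintainers@contactrank.dev")
Description: Predicts protein residue-residue contacts by fusing externally
    computed correlated-mutations score matrices with an ensemble of
    under-sampled random-forest classifiers trained on windowed sequence
    features, then re-ranking residue pairs per protein with a pairwise
    ranking support vector machine (linear kernel, hinge loss).  Includes
    CASP-style range-stratified evaluation (Top 5, L/10, L/5 precision),
    readers for PSI-BLAST ASCII profiles and CASP RR files, and a
    deterministic synthetic-fixture generator for end-to-end testing
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
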
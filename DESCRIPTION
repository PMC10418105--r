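Package: leakforensics
Title: Forensics for Contaminated Metagenomic Count Matrices and Normalization Label Leakage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to demonstrate and diagnose two failure modes of
    host-associated metagenomic classification studies: inflation of
    microbial read counts caused by host-contaminated draft genomes in a
    k-mer classification database, and machine-learning label leakage
    introduced by misapplied supervised normalization of count matrices.
    Includes a fully synthetic data generator (genomes, contaminated
    drafts, reads with provenance, negative-binomial count matrices), a
    minimal exact 31-mer lowest-common-ancestor read classifier, a voom
    style log-CPM transform with explicitly labeled leaky misuse modes,
    matrix forensics statistics (entry-level inflation reports, duplicate
    value tags, single-feature threshold rules), and a one-vs-all
    gradient-boosted classifier evaluation on information-free data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils,
    xgboost
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
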
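Package: aasig
Title: Amino Acid Substitution Signatures from Somatic Mutation Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Extracts amino acid substitution signatures (AAS) from cohorts
    of somatic missense mutations by non-negative matrix factorisation with
    consensus-based rank selection; projects trinucleotide-context
    single-base substitution (SBS) signatures onto coding sequence by
    simulating missense mutations; derives entropy-weighted amino acid
    specificity profiles for HLA class I alleles from immunopeptidomes;
    computes association statistics linking substitution signatures to
    neopeptide detection (weighted-sum association strength, ROC/AUC),
    physicochemical impact summaries, and the CFSE division index. Includes
    seeded synthetic-data generators with planted ground truth for every
    input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    cluster,
    jsonlite,
    Biostrings,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
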
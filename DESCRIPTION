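Package: coevsel
Title: Codon-Model Selection Profiles and Ligand-Receptor Coevolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood codon substitution modelling (GY94-style
    rate matrices with M0/M7/M8/M8a and branch-site A omega mixtures),
    likelihood-ratio tests for positive selection, Naive and Bayes
    Empirical Bayes site posteriors, per-gene selection profiles and
    their ligand-receptor concordance, receptor-domain mapping of
    selected codons, and qPCR delta-delta-Ct expression integration,
    with seeded simulators for codon alignments, coevolving gene pairs
    and Ct tables. Developed for relaxin-family (RLN/INSL-RXFP)
    ligand-receptor pairing analyses in teleosts and mammals.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
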
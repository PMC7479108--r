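Package: exprevo
Title: Phylogenetic Analysis of Gene Expression Evolution Across Organs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the evolution of organ-wise gene expression
    on gene family trees. Amalgamates heterogeneous bulk RNA-seq samples
    into per-species organ expression profiles (TMM scaling, iterative
    removal of anomalous projects, surrogate variable correction), dates
    gene trees with reconciliation-derived age constraints, detects shifts
    of optimal expression levels under multi-optima Ornstein-Uhlenbeck
    models with a group-Lasso plus AICc model search, classifies shifts by
    the preceding branching event (speciation, DNA-based duplication,
    retrotransposition), and computes downstream statistics: organ
    specificity (tau), expression complementarity (TEC), primary-expressed
    organ transition matrices with permutation nulls, global polarity, and
    dN/dS comparisons. A synthetic-data module generates truth-known inputs
    with the same statistical structure so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    edgeR,
    limma,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
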
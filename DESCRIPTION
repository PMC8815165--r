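Package: mpblup
Title: Exact Solving Strategies for Multi-Population Genomic Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact (inversion-based) genomic evaluation for multiple
    populations with correlated additive and dominance SNP effects.
    Implements four numerically equivalent solving strategies: SNP-BLUP
    mixed-model equations in marker effects, standard multiple-trait GBLUP,
    a compact individual-level GBLUP, and generalized least squares with
    selection-index backsolving of marker effects, including a matrix-free
    variant. Ships a multi-population genotype and phenotype simulator
    (Balding-Nichols allele-frequency divergence, optional crossbreds),
    prediction-error variances and reliabilities, blending of singular
    covariance matrices, indirect prediction of newly genotyped
    individuals, and a cross-method equivalence checker.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
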
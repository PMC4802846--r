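Package: geqtl
Title: Group-Wise and Individual Association Mapping for eQTL Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sparse multi-task regression for expression quantitative trait
    locus (eQTL) mapping that decouples SNP-gene associations into individual
    effects and a low-rank group-wise product while correcting hidden
    confounders with a nuclear-norm penalty. Provides Lasso and
    low-rank-plus-sparse (LORS-style) baselines; three model variants with
    l1-penalized, correlation-screened, or closed-form ridge individual
    effects; singular-value-gap selection of the number of group-wise
    associations; permutation-based false discovery rate estimation; a
    simulation generator with block group-wise structure, a cis diagonal and
    latent confounders; and partial-ROC and reproducibility evaluation
    utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), glmnet, jsonlite, optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
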
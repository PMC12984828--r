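Package: dysbioformer
Title: Permutation-Invariant Multiset Transformer for Microbiome Disease
    Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end gut-microbiome disease classification from taxon
    count tables. Implements an amplicon error-model denoiser with chimera
    removal, compositional normalization (zero replacement, cumulative sum
    scaling, centered log-ratio transform), empirical-Bayes cross-study
    batch harmonization, phylogenetic kernel embedding of taxa, and a
    permutation-invariant multiset transformer (stacked Set Attention
    Blocks with Pooling-by-Multihead-Attention) trained by backpropagation,
    together with leakage-safe study-aware cross-validation and
    attention-based taxonomic biomarker attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse,
    biomformat
Config/testthat/edition: 3
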
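Package: momfa
Title: Longitudinal Multi-Omics Factor Analysis for Dystrophic Mouse Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for integrating longitudinal multi-omic studies
    of dystrophic mouse models: simulation of four-view studies (muscle and
    blood RNA-seq counts, plasma lipid and metabolite abundances) with known
    latent structure; per-view preprocessing (low-expression filtering,
    trimmed-mean-of-M-values scale factors, counts-per-million, probabilistic
    quotient normalization, variance-based feature selection, unit-variance
    scaling); matching of samples into multiomic profiles with per-view
    missingness; a multi-view latent factor decomposition Y_m = Z W_m + E_m
    fitted by mean-field variational Bayes with automatic relevance
    determination and variance-threshold factor pruning; ensemble model
    training over a threshold-by-seed grid with ELBO-based best-per-K
    selection and an elbow rule on total variance explained; and association
    of latent factors with genotype group and week via linear models, F tests,
    Benjamini-Hochberg adjustment, pairwise contrasts and loading summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
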
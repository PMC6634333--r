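Package: knnorms
Title: Extrapolating Lexical Norms by k-Nearest Neighbors over
    PPMI-Weighted Similarities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts lexical norms (valence, arousal, dominance, age of
    acquisition, concreteness) for unrated words from the mean norm of
    their k nearest neighbors, with similarity defined as the cosine
    between PPMI-weighted rows of word-by-context count matrices built
    from continued free-association records or word co-occurrence
    counts.  Includes leave-one-out and train/test cross-validation over
    a grid of k, an evaluation battery (Fisher confidence intervals,
    split-half reliability with Spearman-Brown correction, correction
    for attenuation, residual incremental R-squared, tests for
    independent and dependent overlapping correlations), a synthetic
    lexicon generator for end-to-end validation without external data,
    and a configuration-driven study runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
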
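Package: lsaminer
Title: Latent Semantic Analysis of Open-Ended Survey Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines open-ended survey responses with latent semantic analysis
    (LSA). Builds a rank-k semantic space from a background corpus by
    truncated singular value decomposition of a log-entropy weighted
    term-document matrix, removes meaningless ("null") responses by
    exact pattern matching, clusters high-frequency terms around medoids
    (PAM), assigns responses to areas of concern by cosine similarity to
    cluster medoids, and models responder propensity with multivariable
    logistic regression (adjusted odds ratios with Wald intervals) plus
    Cohen's kappa for agreement with human review. Ships a synthetic-cohort
    generator with planted topics and known response-propensity
    coefficients so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    mclust,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
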
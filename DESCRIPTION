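Package: hmmc
Title: Hidden Markov Model Clustering of Tumour Copy-Number Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies tumour subtypes from segmented array-CGH DNA
    copy-number data by clustering samples with a mixture of hidden Markov
    models (HMMC). Each candidate cluster is scored by the Viterbi
    log-likelihood of a shared six-state copy-number chain with lognormal
    emissions; cluster labels are optimized by a stochastic two-sample
    relabelling search seeded by nonnegative matrix factorization, the
    number of clusters is chosen by BIC, and clustering stability is
    assessed by leave-k-out cross-validation. Includes utilities to build a
    common segment grid from per-sample segmentation output, a random-forest
    quality-control filter for normal-tissue contamination, and a simulator
    of two-group copy-number cohorts with AR(1)-correlated noise for
    benchmarking against plain NMF clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
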
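Package: targetfish
Title: Ligand-Based Target Prediction with Single- and Multi-Label Naive Bayes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ligand-based target fishing over binary molecular fingerprints
    using Bernoulli naive Bayes with Laplace correction. Implements a
    single-label multi-class classifier (SMM) with shared-evidence posteriors
    and a binary-relevance multi-label multi-class classifier (MMM) with
    thresholded union prediction, together with the evaluation protocol that
    compares them: example-based and per-class recall/precision with a top-1
    restriction, paired label-rank comparison, McNemar's test and the Wilcoxon
    signed-rank test, plus cross-validated tuning of the posterior threshold.
    A synthetic bipartite activity-data generator with class-conditional
    Bernoulli fingerprints and controlled ligand promiscuity makes every stage
    testable without external bioactivity databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
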
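Package: syndforest
Title: Multi-Label Syndrome Differentiation with Deep Forest Cascades
Version: 0.1.0
Authors@R:
    person("syndforest", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Multi-label classification of clinical symptom records into
    co-occurring syndrome labels. Combines a Pearson-similarity multi-label
    ReliefF filter (similarity-weighted hit/miss neighbourhoods over label
    sets) with a deep forest cascade whose layers hold two multi-label
    forest groups (predictive-clustering and per-label Gini trees), with
    measure-aware feature reuse and measure-aware layer growth. Ships the
    eleven standard multi-label evaluation measures, TF-IDF vectorization
    of symptom term records, a synonym standardizer, a synthetic
    clinical-record generator with planted informative features, and a
    cross-validated end-to-end pipeline with an ablation mode.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
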
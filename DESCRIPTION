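Package: temponet
Title: Causal Network Inference from Pooled Short Gene-Expression Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers directed gene regulatory relationships from many short,
    per-individual expression time series by pooling them into a virtual long
    series. Provides a first-order bivariate autoregressive (BVAR) simulator
    with permutation nulls, baseline re-referencing of per-individual
    profiles, a pooled Granger causality F-test, genome-wide network
    construction with multiple-testing control, indirect-link pruning and
    regulator ranking, bootstrap edge confidence by resampling individuals,
    and a two-slice dynamic Bayesian network learner that holds a supplied
    intra-slice network fixed and learns inter-slice links by BIC-scored
    greedy search with restart consensus. Includes a simulation-experiment
    harness for power versus series length, sampling interval and pooling,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
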
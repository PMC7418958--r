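Package: leviathan
Title: Two-Group Influence-Leviathan Model of Esteem and Status Dynamics
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based simulation of status hierarchy formation through
    pairwise esteem exchange. A population of agents, differing only in an
    "open-mindedness" parameter that sets how strongly credibility depends on
    perceived relative status, interact in random pairs, influence each
    other's self-esteem and mutual esteem through a logistic influence
    function, and gossip about third parties under communication noise. The
    package provides the compiled simulation engine with a naive reference
    implementation, the full indicator suite (reputation, self-esteem
    aggregates, variation coefficients, consensual stratification, social
    ranks, rank-occupancy and advancement probabilities, glass-ceiling
    threshold, extreme-rank Z-scores), scripted experiment designs
    (baseline-versus-two-group sigma sweeps, glass-ceiling analysis,
    group-size by gossip sweeps), configuration files and CSV/JSON output
    with run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
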
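Package: regmotif
Title: Regulatory Motif Detection in Signed Directed Signaling Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects regulatory motifs (oscillation, adaptation, bistable
    switch) in signed directed signaling networks. The network is first
    compressed by node-based reduction that collapses regulatory cascades
    into sign-composed bypass edges while preserving sign dynamics; all
    induced occurrences of compressed 2-3-node query motifs are then found
    with an ESU subgraph enumeration pruned by a path-tree, a trie over
    canonical labels of all isomorphs of the query motifs; finally matches
    are expanded back to full-size motif instances in the original network
    with per-edge sign, path-length and size annotation. Includes a built-in
    compressed motif library, synthetic network generators and a brute-force
    matching oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
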
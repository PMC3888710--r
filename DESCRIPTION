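Package: walkrank
Title: Random-Walk Influence Scoring for Protein Regulatory Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Scores the influence of each protein in a directed
    protein-protein interaction network on a hub interaction (such as
    p53-MDM2) using a random walk with restart. The network is augmented
    with an artificial initial node S (restart / external inflow) and a
    transition node T (exit to external proteins), the uniform transition
    matrix of the walk is built, ergodicity (strong connectivity and
    aperiodicity) is verified, and the Markov-chain stationary
    distribution is solved directly as the eigenvector of the transposed
    transition matrix at eigenvalue one, with power iteration as an
    independent cross-check. Stationary probabilities restricted to the
    protein nodes and renormalized give per-protein influence
    percentages, compared against the uniform 1/n baseline. Includes a
    Monte Carlo walk simulator as an implementation-independent oracle,
    a two-stage group-then-rescore procedure for large networks, file
    readers for edge-list, SIF and adjacency formats, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
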
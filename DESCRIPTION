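Package: ocrank
Title: Ranking Influential Spreaders via Overlapping Communities and Structural Holes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies influential spreader nodes in undirected networks by
    combining overlapping community structure with Burt's network constraint
    coefficient. Overlapping communities are detected with the BIGCLAM
    community-affiliation model (nonnegative factor matrix fitted by projected
    gradient ascent); each node's two-hop neighbourhood is then scored by the
    community multiplicity of its neighbours weighted by their structural-hole
    constraint (the OC score). Includes the standard comparison centralities
    (degree, betweenness, closeness, eigenvector, k-shell, neighbourhood
    coreness), a discrete-time SIR epidemic simulator with Monte-Carlo
    influence estimation and epidemic-threshold computation, Kendall tau-b
    rank-correlation evaluation harnesses, and a synthetic affiliation-graph
    generator with planted overlapping communities for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
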
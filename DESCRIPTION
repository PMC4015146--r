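Package: netprio
Title: Entity Prioritization by Flow Propagation over Heterogeneous Biological Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrates an arbitrary collection of intra-domain biological
    networks (e.g. protein interactions, phenotype similarities, protein
    domain co-occurrence) linked by bipartite inter-domain relation networks
    into a single heterogeneous global graph, and ranks the entities of a
    target network by their inferred association with a user-supplied query
    set. Label values are diffused within each network by degree-normalized
    flow propagation (iterative or closed form), pushed between networks by
    neighbor averaging with noise thresholding, and candidate targets are
    scored by the Pearson correlation between query-propagated projections
    and target-propagated profiles along every simple path of networks.
    Includes a leave-one-out benchmark harness with rank-based ROC/AUC and
    a seeded generator of synthetic heterogeneous networks with planted
    associations for testing and method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
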
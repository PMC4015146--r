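# netprio

Entity prioritization by flow propagation over heterogeneous biological
networks.

## What it does

Biological evidence rarely lives in one network. Gene-disease prioritization
typically draws on a phenotype-similarity network, a protein-interaction
network, perhaps a protein-domain network, linked by bipartite relations
(gene-phenotype annotations, protein-domain assignments). `netprio`
integrates such a *network of networks* — intra-domain graphs
`D_i = (V_i, E_i)` joined by bipartite relations `R_ij` — and ranks the
entities of a chosen target network by their inferred association with a
query set held in another network. It is written for computational
biologists running candidate prioritization (disease genes, candidate
phenotypes, protein domains) from R or from the shell.

The core procedure:

1. **Degree normalization.** Every adjacency `N` is normalized entrywise as
   `N_jk / sqrt(rowsum_j * colsum_k)`, bounding the spectrum by 1 and
   damping hubs.
2. **Flow propagation within a network.** From the prior `x0` (the query
   indicator, normalized to total 1), solve
   `x = (1 - a) (I - a M)^{-1} x0`, or iterate
   `x <- a M x + (1 - a) x0` until the largest change is below `kappa`.
3. **Propagation between networks.** Along every simple path of networks
   from query to target, each next-network node receives the mean value of
   its cross-network neighbors; the lowest `ceiling(n (1 - gamma))` values
   are zeroed, the survivors renormalized and propagated within that
   network.
4. **Correlation scoring.** Each path's penultimate state is projected onto
   target nodes through the normalized relation matrix; a candidate `e` is
   scored by the Pearson correlation between the concatenated projections
   and its own propagated profile, and candidates are ranked by decreasing
   score.

A leave-one-out benchmark harness (rank-based ROC/AUC, normalized mean
rank) and a seeded generator of synthetic heterogeneous networks with
planted associations are included; the methods vignette
(`vignettes/heterogeneous-prioritization.Rmd`) documents the model,
parameter choices and the generator's design.

## Worked example

Generate a small synthetic heterogeneous graph (three domains, chain plus a
direct query-target relation, three planted associations), rank candidates
for one query entity, then benchmark all planted pairs by leave-one-out:

```r
library(netprio)

spec <- fixture_spec(n_domains = 3, sizes = c(60, 50, 40),
                     topology = rbind(c(1, 2), c(2, 3), c(1, 3)),
                     intra_density = 0.1, inter_density = 0.05,
                     planted_pairs = 3, seed = 42)
fix <- generate_hetnet(spec)
fix$graph
#> <global_graph> 3 networks, 3 relations
#>   d1: 60 nodes
#>   d2: 50 nodes
#>   d3: 40 nodes
#>   relations: d1~d2, d2~d3, d1~d3

params  <- propagation_params(gamma = 0.15)  # gamma rescaled for small networks
ranking <- prioritize(fix$graph, fix$pairs$query_entity[1], "d1", "d3", params)
print(ranking, n = 5)
#> <netprio_ranking> 40 candidates, 2 network path(s)
#>  rank  entity     score
#>     1 d3_n006 0.6888464
#>     2 d3_n031 0.1829760
#>     3 d3_n019 0.1744534
#>     4 d3_n023 0.1692570
#>     5 d3_n015 0.1575281
#> ... 35 more
```

The top-ranked entity `d3_n006` is the planted partner of the query
`d1_n034`, scored far above the background (0.69 vs. ~0.18): its propagated
profile correlates with the query signal arriving over both network paths
(`d1 > d3` and `d1 > d2 > d3`). The benchmark removes each planted arc,
re-ranks, and summarizes the achieved ranks:

```r
report <- run_loo(fix$graph, fix$pairs, "d1", "d3", params)
report
#> <netprio_benchmark> 3 trials, 40 candidates each
#>   AUC                  1.0000
#>   normalized mean rank 0.0250 +/- 0.0000
#>   rank 1 achieved in   3/3 trials
```

Even with the direct arcs removed, every true target is recovered at rank 1
out of 40 candidates (AUC 1.0; normalized mean rank 1/40 = 0.025).

Graphs can also be read from/written to plain TSV edge lists
(`read_global_graph()`, `write_global_graph()`), and a command-line front
end with `prioritize`, `benchmark` and `simulate` subcommands is installed
under `inst/cli/netprio`, driven by a YAML run configuration
(`load_config()`).

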
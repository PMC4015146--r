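# builders for small graphs used across the suite; all randomness is local
# to a seed passed in, so tests are reproducible

random_symmetric_network <- function(id, n, density = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- matrix(0, n, n)
  up <- which(upper.tri(w))
  on <- up[runif(length(up)) < density]
  w[on] <- runif(length(on))
  w <- w + t(w)
  domain_network(id, sprintf("%s_%03d", id, seq_len(n)), weights = w)
}

# 2-network graph: query network, target network, one bipartite relation
random_two_net_graph <- function(n_q = 15, n_t = 12, seed = 1,
                                 inter_density = 0.3) {
  set.seed(seed)
  dq <- random_symmetric_network("q", n_q)
  dt <- random_symmetric_network("t", n_t)
  grid <- expand.grid(from = dq$nodes, to = dt$nodes, stringsAsFactors = FALSE)
  grid <- grid[runif(nrow(grid)) < inter_density, ]
  grid$weight <- runif(nrow(grid))
  global_graph(list(dq, dt), list(relation_network(dq, dt, grid)))
}

# deterministic 3-network chain with tiny hand-checkable networks
tiny_chain_graph <- function() {
  da <- domain_network("A", c("a1", "a2", "a3"),
                       data.frame(from = c("a1", "a2"), to = c("a2", "a3"),
                                  weight = c(1, 0.5)))
  db <- domain_network("B", c("b1", "b2", "b3", "b4"),
                       data.frame(from = c("b1", "b2", "b3"),
                                  to = c("b2", "b3", "b4"),
                                  weight = c(1, 1, 0.25)))
  dc <- domain_network("C", c("c1", "c2", "c3"),
                       data.frame(from = "c1", to = "c2", weight = 1))
  rab <- relation_network(da, db,
                          data.frame(from = c("a1", "a2", "a3"),
                                     to = c("b1", "b2", "b2"),
                                     weight = c(1, 0.5, 0.75)))
  rbc <- relation_network(db, dc,
                          data.frame(from = c("b2", "b4", "b3"),
                                     to = c("c1", "c3", "c2"),
                                     weight = c(1, 0.5, 0.8)))
  global_graph(list(da, db, dc), list(rab, rbc))
}

# scalar-loop reference for the degree normalization (independent of Matrix)
normalize_oracle <- function(raw) {
  raw <- as.matrix(raw)
  out <- matrix(0, nrow(raw), ncol(raw))
  rs <- rowSums(raw); cs <- colSums(raw)
  for (j in seq_len(nrow(raw)))
    for (k in seq_len(ncol(raw)))
      if (rs[j] > 0 && cs[k] > 0)
        out[j, k] <- raw[j, k] / sqrt(rs[j] * cs[k])
  out
}

# random meta-graph as an edge matrix over nd domain ids
random_meta_edges <- function(nd, p = 0.5) {
  ids <- paste0("D", seq_len(nd))
  pairs <- t(utils::combn(ids, 2))
  pairs[runif(nrow(pairs)) < p, , drop = FALSE]
}

# build a global_graph with trivial 1-node domains realizing a meta topology
meta_only_graph <- function(edges, nd) {
  ids <- paste0("D", seq_len(nd))
  domains <- lapply(ids, function(id)
    domain_network(id, paste0(tolower(id), "_1")))
  names(domains) <- ids
  relations <- apply(edges, 1, function(e)
    relation_network(domains[[e[1]]], domains[[e[2]]],
                     data.frame(from = domains[[e[1]]]$nodes,
                                to = domains[[e[2]]]$nodes, weight = 1)))
  global_graph(domains, relations)
}

# the acceptance benchmark conditions: one 3-domain graph (chain plus the
# direct query-target relation), 50 planted associations
benchmark_spec <- function(seed) {
  fixture_spec(n_domains = 3, sizes = c(650, 400, 120),
               topology = rbind(c(1, 2), c(2, 3), c(1, 3)),
               intra_density = 0.01, inter_density = 0.005,
               planted_pairs = 50, n_helpers = 4, n_relays = 3,
               signal_strength = 10, noise = 0, seed = seed)
}

benchmark_params <- function() propagation_params(gamma = 0.1)

# pull the edge list back out of a sparse weight matrix
edges_of_matrix <- function(m, undirected) {
  m <- methods::as(methods::as(m, "generalMatrix"), "TsparseMatrix")
  i <- m@i + 1L; j <- m@j + 1L; x <- m@x
  if (undirected) {
    keep <- i <= j
    i <- i[keep]; j <- j[keep]; x <- x[keep]
  }
  data.frame(from = rownames(m)[i], to = colnames(m)[j], weight = x,
             stringsAsFactors = FALSE)
}

# rebuild a global graph with one domain's node order randomly permuted;
# edge lists are order-free, so only the canonical index changes
permute_domain <- function(graph, id) {
  domains <- lapply(graph$domains, function(d) {
    nodes <- if (d$id == id) sample(d$nodes) else d$nodes
    domain_network(d$id, nodes, edges_of_matrix(d$weights, undirected = TRUE))
  })
  relations <- lapply(graph$relations, function(r)
    relation_network(domains[[r$source_id]], domains[[r$target_id]],
                     edges_of_matrix(r$weights, undirected = FALSE)))
  global_graph(domains, unname(relations))
}
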
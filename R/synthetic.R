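#' Specification of a synthetic heterogeneous network
#'
#' Describes a randomly generated network-of-networks with planted
#' query-target associations, used as a fully reproducible test bed: fixing
#' `seed` fixes the generated graph byte for byte.
#'
#' Background edges are drawn independently with the stated densities and
#' uniform `(0, 1]` weights.  For each planted association a high-weight
#' route is embedded through *every* meta-graph path joining the query and
#' target domains: the query entity is tied to a small clique of helper
#' nodes, each intermediate domain on a path receives dedicated relay nodes
#' (strongly interconnected), and consecutive layers are joined by relation
#' arcs, ending in arcs into the planted target.  Planted weights are the
#' uniform baseline scaled by `signal_strength` and capped at 1, keeping all
#' weights in the `[0, 1]` similarity convention.
#'
#' @param n_domains Number of domain networks (ids `d1`, `d2`, ...).
#' @param sizes Integer vector of nodes per network (recycled to
#'   `n_domains`).
#' @param topology 2-column integer matrix of meta-graph edges (domain
#'   indices); default is a chain `1-2, 2-3, ...`.
#' @param intra_density,inter_density Independent edge probabilities for
#'   background intra-network and relation edges.
#' @param planted_pairs Number of query-target associations to plant (query
#'   entities drawn from `query_domain`, targets from `target_domain`,
#'   without replacement).
#' @param query_domain,target_domain Domain indices of the planted pairs.
#' @param n_helpers,n_relays Size of the planted query clique and of the
#'   relay set per intermediate domain.
#' @param signal_strength Weight multiplier on planted arcs (capped at 1).
#' @param noise Probability of additional spurious edges, applied on top of
#'   the background everywhere.
#' @param seed RNG seed; one private stream per fixture.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_domains = 3, sizes = 60, topology = NULL,
                         intra_density = 0.1, inter_density = 0.05,
                         planted_pairs = 1, query_domain = 1,
                         target_domain = n_domains,
                         n_helpers = 2, n_relays = 2,
                         signal_strength = 10, noise = 0, seed = 1) {
  sizes <- rep_len(as.integer(sizes), n_domains)
  if (is.null(topology)) {
    topology <- cbind(seq_len(n_domains - 1), 2:n_domains)
  }
  topology <- matrix(as.integer(topology), ncol = 2)
  if (any(topology < 1 | topology > n_domains))
    stop("topology references an unknown domain index")
  probs <- c(intra_density, inter_density, noise)
  if (any(probs < 0 | probs > 1))
    stop("densities and noise must be probabilities in [0, 1]")
  stopifnot(query_domain %in% seq_len(n_domains),
            target_domain %in% seq_len(n_domains),
            query_domain != target_domain)
  structure(list(n_domains = n_domains, sizes = sizes, topology = topology,
                 intra_density = intra_density, inter_density = inter_density,
                 planted_pairs = planted_pairs, query_domain = query_domain,
                 target_domain = target_domain, n_helpers = n_helpers,
                 n_relays = n_relays, signal_strength = signal_strength,
                 noise = noise, seed = seed),
            class = "fixture_spec")
}

# run code under a private RNG stream, restoring global state afterwards
with_fixture_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic heterogeneous global graph
#'
#' Realizes a [fixture_spec()]: random weighted intra-domain graphs, random
#' bipartite relations following the meta-graph topology, and a reinforced
#' route for every planted association (see [fixture_spec()] for the
#' construction).  Deterministic under the spec's seed.
#'
#' @param spec A `fixture_spec`.
#' @return List with elements `graph` (a `global_graph`) and `pairs` (data
#'   frame of planted associations with columns `query_entity`,
#'   `true_target`).
#' @export
generate_hetnet <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_fixture_rng(spec$seed, {
    nd <- spec$n_domains
    ids <- paste0("d", seq_len(nd))
    node_sets <- lapply(seq_len(nd), function(i)
      sprintf("d%d_n%03d", i, seq_len(spec$sizes[i])))

    intra_edges <- lapply(seq_len(nd), function(i)
      random_pair_edges(node_sets[[i]], spec$intra_density))
    rel_keys <- apply(spec$topology, 1, function(e)
      paste(sort(e), collapse = "-"))
    if (anyDuplicated(rel_keys)) stop("duplicate topology edge")
    inter_edges <- lapply(seq_len(nrow(spec$topology)), function(k) {
      e <- spec$topology[k, ]
      random_bipartite_edges(node_sets[[e[1]]], node_sets[[e[2]]],
                             spec$inter_density)
    })

    # planted associations: module arcs are accumulated separately from the
    # background so that, at zero noise, module source nodes end up carrying
    # exactly their module arcs (a background cross-network arc incident to
    # a query, helper, relay or decoy source is a spurious association; the
    # noise parameter reintroduces such arcs explicitly)
    qd <- spec$query_domain; td <- spec$target_domain
    npairs <- spec$planted_pairs
    pairs <- data.frame(query_entity = character(0), true_target = character(0))
    module_inter <- lapply(seq_len(nrow(spec$topology)), function(k)
      data.frame(from = character(0), to = character(0), weight = numeric(0)))
    module_nodes <- lapply(seq_len(nd), function(i) character(0))
    if (npairs > 0) {
      qs <- sample(node_sets[[qd]], npairs)
      ts <- sample(node_sets[[td]], npairs)
      pairs <- data.frame(query_entity = qs, true_target = ts,
                          stringsAsFactors = FALSE)
      meta_paths <- simple_index_paths(spec$topology, qd, td, nd)
      if (length(meta_paths) == 0)
        stop("topology does not connect the query and target domains")
      w_s <- function(n) pmin(1, spec$signal_strength * stats::runif(n))
      add_module_arcs <- function(nodes_a, nodes_b, a, b) {
        grid <- expand.grid(from = nodes_a, to = nodes_b,
                            stringsAsFactors = FALSE)
        grid$weight <- w_s(nrow(grid))
        k <- match(paste(sort(c(a, b)), collapse = "-"), rel_keys)
        if (spec$topology[k, 1] != a) # relation stored source = topology[,1]
          grid <- data.frame(from = grid$to, to = grid$from,
                             weight = grid$weight, stringsAsFactors = FALSE)
        module_inter[[k]] <<- rbind(module_inter[[k]], grid)
      }
      # helper/relay nodes are drawn without replacement across pairs so the
      # planted routes stay disjoint and do not feed each other's targets
      pool <- node_sets
      pool[[qd]] <- setdiff(pool[[qd]], qs)
      pool[[td]] <- setdiff(pool[[td]], ts)
      draw <- function(dom, k) {
        k <- min(k, length(pool[[dom]]))
        picked <- if (k > 0) sample(pool[[dom]], k) else character(0)
        pool[[dom]] <<- setdiff(pool[[dom]], picked)
        module_nodes[[dom]] <<- c(module_nodes[[dom]], picked)
        picked
      }
      module_nodes[[qd]] <- qs
      for (p in seq_len(npairs)) {
        q <- qs[p]; t <- ts[p]
        helpers <- draw(qd, spec$n_helpers)
        layer_q <- c(q, helpers)
        intra_edges[[qd]] <- rbind(intra_edges[[qd]],
                                   clique_edges(layer_q, w_s))
        relays <- list()
        for (path in meta_paths) {
          for (dom in path[-c(1, length(path))]) {
            key <- as.character(dom)
            if (is.null(relays[[key]]))
              relays[[key]] <- draw(dom, spec$n_relays)
          }
          for (j in seq_len(length(path) - 1)) {
            a <- path[j]; b <- path[j + 1]
            nodes_a <- if (a == qd) layer_q else relays[[as.character(a)]]
            nodes_b <- if (b == td) t else relays[[as.character(b)]]
            add_module_arcs(nodes_a, nodes_b, a, b)
            if (b != td)
              intra_edges[[b]] <- rbind(intra_edges[[b]],
                                        clique_edges(relays[[as.character(b)]], w_s))
          }
        }
      }

      # decoy neighborhoods: every non-planted target-domain node receives
      # the same number of planted-grade arcs as a planted target, wired to
      # nodes that carry no query signal; candidates then differ by where
      # their neighborhood points, not by how annotated it is
      decoys <- setdiff(node_sets[[td]], ts)
      last_hops <- unique(lapply(meta_paths, function(p)
        c(p[length(p) - 1], p[length(p)])))
      for (hop in last_hops) {
        a <- hop[1]
        n_arcs <- if (a == qd) spec$n_helpers + 1L else spec$n_relays
        # decoy sources are drawn without replacement (pool refilled with the
        # non-signal nodes if exhausted) so their relation degrees match the
        # planted helpers' and the normalization does not favor either side
        non_signal <- pool[[a]]
        if (length(non_signal) == 0) next
        for (di in seq_along(decoys)) {
          if (length(pool[[a]]) < n_arcs)
            pool[[a]] <- union(pool[[a]], non_signal)
          srcs <- draw(a, n_arcs)
          # decoy source groups get the same strong clique a planted module
          # has, so candidates are exchangeable under an unrelated query
          intra_edges[[a]] <- rbind(intra_edges[[a]], clique_edges(srcs, w_s))
          add_module_arcs(srcs, decoys[di], a, td)
        }
      }

      # merge: background arcs incident to a module source node are dropped
      for (k in seq_len(nrow(spec$topology))) {
        e <- spec$topology[k, ]
        bg <- inter_edges[[k]]
        keep <- !(bg$from %in% module_nodes[[e[1]]] |
                  bg$to %in% module_nodes[[e[2]]])
        inter_edges[[k]] <- rbind(bg[keep, , drop = FALSE], module_inter[[k]])
      }
    }

    # spurious extra edges
    if (spec$noise > 0) {
      for (i in seq_len(nd))
        intra_edges[[i]] <- rbind(intra_edges[[i]],
                                  random_pair_edges(node_sets[[i]], spec$noise))
      for (k in seq_len(nrow(spec$topology))) {
        e <- spec$topology[k, ]
        inter_edges[[k]] <- rbind(inter_edges[[k]],
                                  random_bipartite_edges(node_sets[[e[1]]],
                                                         node_sets[[e[2]]],
                                                         spec$noise))
      }
    }

    domains <- lapply(seq_len(nd), function(i)
      domain_network(ids[i], node_sets[[i]], dedupe_edges(intra_edges[[i]])))
    names(domains) <- ids
    relations <- lapply(seq_len(nrow(spec$topology)), function(k) {
      e <- spec$topology[k, ]
      relation_network(domains[[e[1]]], domains[[e[2]]],
                       dedupe_edges(inter_edges[[k]], ordered = TRUE))
    })
    list(graph = global_graph(domains, relations), pairs = pairs)
  })
}

random_pair_edges <- function(nodes, density) {
  n <- length(nodes)
  if (n < 2 || density == 0)
    return(data.frame(from = character(0), to = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(idx)) < density
  idx <- idx[keep, , drop = FALSE]
  data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
             weight = stats::runif(nrow(idx)), stringsAsFactors = FALSE)
}

random_bipartite_edges <- function(nodes_a, nodes_b, density) {
  if (density == 0)
    return(data.frame(from = character(0), to = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  grid <- expand.grid(from = nodes_a, to = nodes_b, stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(grid)) < density
  grid <- grid[keep, , drop = FALSE]
  grid$weight <- stats::runif(nrow(grid))
  grid
}

clique_edges <- function(nodes, w_fun) {
  if (length(nodes) < 2)
    return(data.frame(from = character(0), to = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  idx <- utils::combn(length(nodes), 2)
  data.frame(from = nodes[idx[1, ]], to = nodes[idx[2, ]],
             weight = w_fun(ncol(idx)), stringsAsFactors = FALSE)
}

# keep the strongest weight when the same arc was drawn twice; intra-network
# arcs are unordered pairs, bipartite arcs keep their orientation
dedupe_edges <- function(edges, ordered = FALSE) {
  if (nrow(edges) == 0) return(edges)
  if (ordered) {
    a <- edges$from; b <- edges$to
  } else {
    a <- pmin(edges$from, edges$to)
    b <- pmax(edges$from, edges$to)
  }
  key <- paste(a, b, sep = "\x01")
  keep <- !duplicated(key)
  out <- data.frame(from = a[keep], to = b[keep], weight = NA_real_,
                    stringsAsFactors = FALSE)
  out$weight <- vapply(split(edges$weight, key)[unique(key)], max, numeric(1))
  out
}

# all simple paths between two vertices of a small undirected index graph
simple_index_paths <- function(topology, from, to, n) {
  adj <- lapply(seq_len(n), function(v)
    sort(unique(c(topology[topology[, 1] == v, 2],
                  topology[topology[, 2] == v, 1]))))
  paths <- list()
  walk <- function(v, seen) {
    if (v == to) { paths[[length(paths) + 1L]] <<- seen; return(invisible()) }
    for (w in adj[[v]]) if (!w %in% seen) walk(w, c(seen, w))
  }
  walk(from, from)
  paths
}

#' Shuffle the targets of an association list
#'
#' Permutes the `true_target` column uniformly at random (identity
#' permutations allowed), producing the label-shuffled null control used to
#' check that a benchmark's signal is real.
#'
#' @param pairs Data frame with columns `query_entity`, `true_target`.
#' @param seed RNG seed (private stream).
#' @return The pair list with permuted targets.
#' @export
shuffle_labels <- function(pairs, seed = 1) {
  if (nrow(pairs) < 2) stop("need at least 2 pairs to shuffle")
  with_fixture_rng(seed, {
    pairs$true_target <- pairs$true_target[sample(nrow(pairs))]
    pairs
  })
}
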
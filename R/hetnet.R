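#' Construct an intra-domain network
#'
#' A domain network holds the entities of one biological domain (genes,
#' diseases, protein domains, ...) and a weighted undirected graph over them.
#' The degree-normalized adjacency used by the propagation engine is computed
#' eagerly at construction time.
#'
#' @param id Unique network name (character scalar).
#' @param nodes Character vector of unique entity identifiers; its order is
#'   the canonical node index used for all vectors, matrices and tie-breaking.
#' @param edges Optional data frame with columns `from`, `to`, `weight`
#'   listing each undirected edge once (self-loops allowed; they enter the
#'   degree sums like any other weight).
#' @param weights Optional symmetric nonnegative matrix over `nodes`,
#'   alternative to `edges`.
#' @return An object of class `domain_network` with elements `id`, `nodes`,
#'   `weights` (sparse symmetric raw adjacency) and `norm_adjacency`.
#' @examples
#' net <- domain_network("genes", c("g1", "g2", "g3"),
#'                       data.frame(from = "g1", to = "g2", weight = 1))
#' net$norm_adjacency
#' @export
domain_network <- function(id, nodes, edges = NULL, weights = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes))
    stop(sprintf("network '%s': duplicate node identifier '%s'",
                 id, nodes[duplicated(nodes)][1]))
  n <- length(nodes)
  if (is.null(weights)) {
    weights <- edges_to_matrix(edges, nodes, nodes, network = id, symmetrize = TRUE)
  } else {
    weights <- methods::as(methods::as(Matrix::Matrix(weights, sparse = TRUE),
                                       "generalMatrix"), "CsparseMatrix")
    if (nrow(weights) != n || ncol(weights) != n)
      stop(sprintf("network '%s': weight matrix must be %d x %d", id, n, n))
    if (!Matrix::isSymmetric(weights, tol = 0))
      stop(sprintf("network '%s': weight matrix is not symmetric", id))
    dimnames(weights) <- list(nodes, nodes)
  }
  structure(list(id = id, nodes = nodes, weights = weights,
                 norm_adjacency = normalize_adjacency(weights)),
            class = "domain_network")
}

#' Construct a bipartite inter-domain relation network
#'
#' Links two domain networks through weighted arcs between their entities.
#' The raw bipartite adjacency is stored with rows indexed by the source
#' network's nodes and columns by the target network's nodes; use
#' [relation_matrix()] to obtain either orientation of the raw or normalized
#' matrix.
#'
#' @param source,target `domain_network` objects at the two endpoints.
#' @param edges Data frame with columns `from` (source-network node), `to`
#'   (target-network node), `weight`.
#' @return An object of class `relation_network` with elements `source_id`,
#'   `target_id`, `weights` and `norm_adjacency` (same orientation as
#'   `weights`).
#' @export
relation_network <- function(source, target, edges) {
  stopifnot(inherits(source, "domain_network"), inherits(target, "domain_network"))
  if (source$id == target$id)
    stop("a relation must connect two distinct networks")
  w <- edges_to_matrix(edges, source$nodes, target$nodes,
                       network = paste0(source$id, "~", target$id),
                       symmetrize = FALSE)
  structure(list(source_id = source$id, target_id = target$id,
                 weights = w, norm_adjacency = normalize_adjacency(w)),
            class = "relation_network")
}

edges_to_matrix <- function(edges, row_nodes, col_nodes, network, symmetrize) {
  if (is.null(edges) || nrow(edges) == 0L) {
    m <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(length(row_nodes), length(col_nodes)),
                              dimnames = list(row_nodes, col_nodes))
    return(methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix"))
  }
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  i <- match(as.character(edges$from), row_nodes)
  j <- match(as.character(edges$to), col_nodes)
  if (anyNA(i))
    stop(sprintf("edge list for '%s' references unknown node '%s'",
                 network, as.character(edges$from)[which(is.na(i))[1]]))
  if (anyNA(j))
    stop(sprintf("edge list for '%s' references unknown node '%s'",
                 network, as.character(edges$to)[which(is.na(j))[1]]))
  x <- as.numeric(edges$weight)
  if (any(!is.finite(x) | x < 0)) {
    k <- which(!is.finite(x) | x < 0)[1]
    stop(sprintf("edge %s -- %s in '%s' has negative or non-finite weight",
                 edges$from[k], edges$to[k], network))
  }
  if (symmetrize) {
    off <- i != j
    i2 <- c(i, j[off]); j2 <- c(j, i[off]); x2 <- c(x, x[off])
  } else {
    i2 <- i; j2 <- j; x2 <- x
  }
  m <- Matrix::sparseMatrix(i = i2, j = j2, x = x2,
                            dims = c(length(row_nodes), length(col_nodes)),
                            dimnames = list(row_nodes, col_nodes))
  methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
}

#' Assemble the heterogeneous global graph
#'
#' Combines a set of domain networks and the bipartite relations between
#' them into a single network-of-networks.  Node vocabularies of distinct
#' networks must be disjoint, and at most one relation may exist per
#' unordered pair of networks.  A domain-level meta-graph (one vertex per
#' network, one edge per relation) is stored for path enumeration.
#'
#' @param domains List of `domain_network` objects.
#' @param relations List of `relation_network` objects.
#' @return An object of class `global_graph` with elements `domains` (named
#'   list), `relations` (named by `"<a>~<b>"` with ids sorted), and
#'   `meta_edges` (2-column character matrix).
#' @export
global_graph <- function(domains, relations = list()) {
  if (inherits(domains, "domain_network")) domains <- list(domains)
  if (inherits(relations, "relation_network")) relations <- list(relations)
  ids <- vapply(domains, function(d) d$id, character(1))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate network id '%s'", ids[duplicated(ids)][1]))
  names(domains) <- ids
  all_nodes <- unlist(lapply(domains, `[[`, "nodes"), use.names = FALSE)
  if (anyDuplicated(all_nodes))
    stop(sprintf("node id '%s' appears in more than one network",
                 all_nodes[duplicated(all_nodes)][1]))
  keys <- character(0)
  meta <- matrix(character(0), ncol = 2)
  for (r in relations) {
    if (!r$source_id %in% ids || !r$target_id %in% ids)
      stop(sprintf("relation %s~%s references an undeclared network",
                   r$source_id, r$target_id))
    key <- relation_key(r$source_id, r$target_id)
    if (key %in% keys)
      stop(sprintf("duplicate relation between networks '%s' and '%s'",
                   r$source_id, r$target_id))
    keys <- c(keys, key)
    meta <- rbind(meta, c(r$source_id, r$target_id))
  }
  names(relations) <- keys
  structure(list(domains = domains, relations = relations, meta_edges = meta),
            class = "global_graph")
}

relation_key <- function(a, b) paste(sort(c(a, b)), collapse = "~")

#' Look up the relation connecting two networks
#'
#' @param graph A `global_graph`.
#' @param a,b Network ids (order irrelevant).
#' @return The `relation_network`, or `NULL` if the pair is not connected.
#' @export
find_relation <- function(graph, a, b) {
  graph$relations[[relation_key(a, b)]]
}

#' Oriented (normalized) relation matrix
#'
#' Returns the bipartite adjacency of the relation between `from` and `to`
#' oriented so that rows index `to`'s nodes and columns index `from`'s nodes;
#' multiplying it with a state vector on `from` yields a vector on `to`.
#' Degree normalization is symmetric in row/column sums, so the normalized
#' matrix of one orientation is the transpose of the other.
#'
#' @param graph A `global_graph`.
#' @param from,to Network ids joined by a relation.
#' @param normalized If `TRUE` (default) return the degree-normalized matrix,
#'   otherwise the raw weights.
#' @return A sparse matrix with `length(to$nodes)` rows and
#'   `length(from$nodes)` columns.
#' @export
relation_matrix <- function(graph, from, to, normalized = TRUE) {
  rel <- find_relation(graph, from, to)
  if (is.null(rel))
    stop(sprintf("networks '%s' and '%s' are not joined by a relation", from, to))
  m <- if (normalized) rel$norm_adjacency else rel$weights
  if (rel$source_id == from) Matrix::t(m) else m
}

#' Initial state vector for a seed set
#'
#' Assigns value 1 to each node of `seed_set` and 0 to every other node of
#' the network, in the network's canonical node order.
#'
#' @param network A `domain_network`.
#' @param seed_set Character vector of node ids in the network.
#' @return Named numeric vector of length `length(network$nodes)`.
#' @export
init_state <- function(network, seed_set) {
  seed_set <- as.character(seed_set)
  idx <- match(seed_set, network$nodes)
  if (anyNA(idx))
    stop(sprintf("node '%s' does not belong to network '%s'",
                 seed_set[which(is.na(idx))[1]], network$id))
  v <- stats::setNames(numeric(length(network$nodes)), network$nodes)
  v[idx] <- 1
  v
}

#' Which network does an entity belong to?
#'
#' @param graph A `global_graph`.
#' @param entity A node id.
#' @return The id of the containing network.
#' @export
entity_network <- function(graph, entity) {
  for (d in graph$domains) if (entity %in% d$nodes) return(d$id)
  stop(sprintf("entity '%s' not found in any network", entity))
}

#' @export
print.domain_network <- function(x, ...) {
  cat(sprintf("<domain_network '%s'> %d nodes, %d edges\n", x$id,
              length(x$nodes), (Matrix::nnzero(x$weights) +
                                sum(Matrix::diag(x$weights) != 0)) %/% 2))
  invisible(x)
}

#' @export
print.relation_network <- function(x, ...) {
  cat(sprintf("<relation_network %s ~ %s> %d x %d, %d arcs\n", x$source_id,
              x$target_id, nrow(x$weights), ncol(x$weights),
              Matrix::nnzero(x$weights)))
  invisible(x)
}

#' @export
print.global_graph <- function(x, ...) {
  cat(sprintf("<global_graph> %d networks, %d relations\n",
              length(x$domains), length(x$relations)))
  for (d in x$domains)
    cat(sprintf("  %s: %d nodes\n", d$id, length(d$nodes)))
  if (nrow(x$meta_edges))
    cat("  relations:", paste(x$meta_edges[, 1], x$meta_edges[, 2],
                              sep = "~", collapse = ", "), "\n")
  invisible(x)
}
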
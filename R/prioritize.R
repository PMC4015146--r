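#' Enumerate simple network paths between two domains
#'
#' Finds every simple path in the domain-level meta-graph from the query
#' network to the target network (each network visited at most once) by
#' exhaustive depth-first search.  With the handful of networks typical of
#' heterogeneous integration this brute force is instantaneous.  Paths are
#' returned in lexicographic order of their id sequences, which fixes the
#' concatenation order used downstream.
#'
#' @param graph A `global_graph`.
#' @param query_id,target_id Distinct network ids.
#' @return List of character vectors, each starting at `query_id` and ending
#'   at `target_id`.
#' @export
enumerate_paths <- function(graph, query_id, target_id) {
  ids <- names(graph$domains)
  if (!query_id %in% ids) stop(sprintf("unknown network '%s'", query_id))
  if (!target_id %in% ids) stop(sprintf("unknown network '%s'", target_id))
  if (query_id == target_id)
    stop("query and target networks must be distinct")
  adj <- lapply(stats::setNames(ids, ids), function(v) {
    e <- graph$meta_edges
    sort(unique(c(e[e[, 1] == v, 2], e[e[, 2] == v, 1])))
  })
  paths <- list()
  walk <- function(v, seen) {
    if (v == target_id) {
      paths[[length(paths) + 1L]] <<- seen
      return(invisible())
    }
    for (w in adj[[v]])
      if (!w %in% seen) walk(w, c(seen, w))
  }
  walk(query_id, query_id)
  if (length(paths) == 0L)
    stop(sprintf("query and target networks are disconnected: no path joins '%s' and '%s'",
                 query_id, target_id))
  paths[order(vapply(paths, paste, character(1), collapse = "\x01"))]
}

#' Propagate the query signal along one network path
#'
#' Starting from the query state already propagated within the query network,
#' repeats for every intermediate network on the path: between-network
#' neighbor-mean propagation, gamma-thresholding of the lowest values,
#' prior normalization over the surviving support, and within-network flow
#' propagation.  The state reached on the penultimate network is stored and
#' projected onto the target network's nodes through the normalized relation
#' matrix.  The target network's own values are never touched.  If
#' thresholding leaves an all-zero state (a signal-free route) the zero state
#' is carried forward unchanged.
#'
#' @param graph A `global_graph`.
#' @param path Character vector of network ids (query first, target last).
#' @param query_state_hat Query state after within-network propagation.
#' @param params A `propagation_params`.
#' @return List with elements `path`, `penultimate_state` and `projected`
#'   (numeric vector over target-network nodes).
#' @export
propagate_along_path <- function(graph, path, query_state_hat, params = propagation_params()) {
  l <- length(path)
  stopifnot(l >= 2)
  state <- query_state_hat
  if (l > 2) {
    for (j in seq_len(l - 2)) {
      a <- path[j]; b <- path[j + 1]
      rel <- find_relation(graph, a, b)
      if (is.null(rel))
        stop(sprintf("path step %s -> %s has no relation", a, b))
      state <- propagate_between(state, rel, from = a, to = b)
      state <- apply_gamma_threshold(state, params$gamma)
      if (all(state == 0)) {
        state <- stats::setNames(numeric(length(graph$domains[[b]]$nodes)),
                                 graph$domains[[b]]$nodes)
      } else {
        state <- normalize_prior(state)
        state <- propagate_within(graph$domains[[b]], state, params)
      }
    }
  }
  S_a <- relation_matrix(graph, from = path[l - 1], to = path[l], normalized = TRUE)
  projected <- as.numeric(S_a %*% as.numeric(state))
  names(projected) <- graph$domains[[path[l]]]$nodes
  list(path = path, penultimate_state = state, projected = projected)
}

#' Correlation score between query projections and a target profile
#'
#' Concatenates the target-side projections of every path into one vector
#' and correlates it (Pearson) against the target-propagated profile repeated
#' once per path.  If either concatenated vector has zero variance the score
#' is defined as 0: such a candidate carries no usable evidence and must not
#' produce `NaN` in the ranking.
#'
#' @param path_results List of results from [propagate_along_path()].
#' @param target_state_hat Target state after within-network propagation.
#' @return Correlation score in `[-1, 1]`.
#' @export
score_correlation <- function(path_results, target_state_hat) {
  stopifnot(length(path_results) >= 1)
  xbar <- unlist(lapply(path_results, `[[`, "projected"), use.names = FALSE)
  tbar <- rep(as.numeric(target_state_hat), times = length(path_results))
  if (length(xbar) != length(tbar))
    stop("internal error: projected vectors and target profile have mismatched lengths")
  pearson_or_zero(xbar, tbar)
}

pearson_or_zero <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  dx <- sqrt(sum(xc^2)); dy <- sqrt(sum(yc^2))
  if (dx == 0 || dy == 0) return(0)
  sum(xc * yc) / (dx * dy)
}

#' Rank target-network entities against a query set
#'
#' The full prioritization pipeline: propagate the query set within its
#' network, push the signal along every simple network path to the target
#' network (storing each path's penultimate state and projection), then score
#' every candidate target entity by the Pearson correlation between the
#' concatenated projections and the candidate's own propagated profile, and
#' sort the candidates by decreasing score.
#'
#' The per-candidate target propagation solves the closed form
#' `(1 - alpha) * solve(I - alpha * M_t)` once; its column `e` is exactly the
#' propagated profile of the singleton target set `{e}` (a singleton prior is
#' already normalized), so the loop over candidates is a single matrix
#' factorization followed by column reads.
#'
#' @param graph A `global_graph`.
#' @param query_set Character vector of query entities (all in the query
#'   network).
#' @param query_id,target_id Network ids housing the query set and the
#'   candidates.
#' @param params A `propagation_params`.
#' @return A data frame of class `netprio_ranking` with columns `rank`,
#'   `entity`, `score`, sorted by decreasing score (ties by canonical node
#'   index).  Attributes: `paths` (the enumerated network paths) and
#'   `path_results`.
#' @export
prioritize <- function(graph, query_set, query_id, target_id,
                       params = propagation_params()) {
  if (length(query_set) == 0) stop("query set is empty")
  if (params$alpha >= 1)
    stop("prioritization requires alpha < 1 (alpha = 1 makes I - alpha*M singular)")
  dq <- graph$domains[[query_id]]
  dt <- graph$domains[[target_id]]
  if (is.null(dq)) stop(sprintf("unknown network '%s'", query_id))
  if (is.null(dt)) stop(sprintf("unknown network '%s'", target_id))

  x0q <- normalize_prior(init_state(dq, query_set))
  xq_hat <- propagate_within(dq, x0q, params)

  paths <- enumerate_paths(graph, query_id, target_id)
  path_results <- lapply(paths, propagate_along_path, graph = graph,
                         query_state_hat = xq_hat, params = params)

  xbar <- unlist(lapply(path_results, `[[`, "projected"), use.names = FALSE)
  n_t <- length(dt$nodes)
  # column e of Ft is the propagated profile of target set {e}
  Ft <- (1 - params$alpha) *
    as.matrix(Matrix::solve(Matrix::Diagonal(n_t) - params$alpha * dt$norm_adjacency,
                            diag(n_t)))
  Tbar <- do.call(rbind, rep(list(Ft), length(paths)))

  xc <- xbar - mean(xbar)
  dx <- sqrt(sum(xc^2))
  Tc <- sweep(Tbar, 2, colMeans(Tbar))
  dT <- sqrt(colSums(Tc^2))
  scores <- as.numeric(crossprod(xc, Tc))
  denom <- dx * dT
  scores <- ifelse(denom > 0, scores / denom, 0)
  if (dx == 0) scores[] <- 0

  ord <- order(-scores, seq_len(n_t))
  out <- data.frame(rank = seq_len(n_t), entity = dt$nodes[ord],
                    score = scores[ord], stringsAsFactors = FALSE)
  attr(out, "paths") <- paths
  attr(out, "path_results") <- path_results
  attr(out, "scores") <- stats::setNames(scores, dt$nodes)
  class(out) <- c("netprio_ranking", "data.frame")
  out
}

#' @export
print.netprio_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("<netprio_ranking> %d candidates, %d network path(s)\n",
              nrow(x), length(attr(x, "paths"))))
  print.data.frame(utils::head(x, n), row.names = FALSE)
  if (nrow(x) > n) cat(sprintf("... %d more\n", nrow(x) - n))
  invisible(x)
}
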
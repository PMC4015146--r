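#' Leave-one-out benchmark over known query-target associations
#'
#' For each known association (query entity, true target) the explicit arc
#' joining the pair in the query-target relation is removed (and the
#' relation's normalized matrix recomputed, so the trial cannot leak the
#' removed arc through stale degree normalization), the query entity is
#' prioritized against every target-network candidate, and the rank achieved
#' by the true target is recorded.  The input graph is never modified: each
#' trial runs on a patched copy.
#'
#' With `remove = FALSE` the same protocol scores associations that are
#' absent from the graph by construction (e.g. newly curated pairs), without
#' deleting anything.
#'
#' @param graph A `global_graph`.
#' @param pairs Data frame with columns `query_entity`, `true_target`.
#' @param query_id,target_id Networks housing the query entities and the
#'   candidates.
#' @param params A `propagation_params`.
#' @param remove Delete the direct arc before each trial (default `TRUE`).
#' @return Object of class `netprio_benchmark`: list with `trials` (per-trial
#'   data frame), `auc`, `roc_points`, `normalized_mean_rank`, `rank_std`,
#'   `n_candidates`.
#' @export
run_loo <- function(graph, pairs, query_id, target_id,
                    params = propagation_params(), remove = TRUE) {
  if (is.null(pairs) || nrow(pairs) == 0) stop("no trials: the pair list is empty")
  stopifnot(all(c("query_entity", "true_target") %in% names(pairs)))
  dq <- graph$domains[[query_id]]
  dt <- graph$domains[[target_id]]
  rel <- find_relation(graph, query_id, target_id)
  if (remove) {
    if (is.null(rel))
      stop(sprintf("no relation joins '%s' and '%s'; cannot remove arcs",
                   query_id, target_id))
    for (k in seq_len(nrow(pairs))) {
      q <- as.character(pairs$query_entity[k])
      t <- as.character(pairs$true_target[k])
      if (get_arc_weight(rel, q, t) == 0)
        stop(sprintf("pair %s -- %s is not an existing arc in relation %s~%s",
                     q, t, rel$source_id, rel$target_id))
    }
  }
  n_t <- length(dt$nodes)
  ranks <- integer(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    q <- as.character(pairs$query_entity[k])
    t <- as.character(pairs$true_target[k])
    g_trial <- if (remove) remove_relation_arc(graph, query_id, target_id, q, t) else graph
    rk <- prioritize(g_trial, q, query_id, target_id, params)
    ranks[k] <- rk$rank[match(t, rk$entity)]
  }
  trials <- data.frame(query_entity = as.character(pairs$query_entity),
                       true_target = as.character(pairs$true_target),
                       rank = ranks, n_candidates = n_t,
                       stringsAsFactors = FALSE)
  nmr <- normalized_mean_rank(ranks, n_t)
  structure(list(trials = trials,
                 auc = rank_based_auc(ranks, n_t),
                 roc_points = rank_roc_points(ranks, n_t),
                 normalized_mean_rank = nmr$mean,
                 rank_std = nmr$sd,
                 n_candidates = n_t),
            class = "netprio_benchmark")
}

get_arc_weight <- function(rel, q, t) {
  # orientation: q may live on either side of the stored matrix
  if (q %in% rownames(rel$weights) && t %in% colnames(rel$weights))
    return(rel$weights[q, t])
  if (t %in% rownames(rel$weights) && q %in% colnames(rel$weights))
    return(rel$weights[t, q])
  0
}

remove_relation_arc <- function(graph, a, b, node_a, node_b) {
  key <- relation_key(a, b)
  rel <- graph$relations[[key]]
  w <- rel$weights
  if (node_a %in% rownames(w)) {
    w[node_a, node_b] <- 0
  } else {
    w[node_b, node_a] <- 0
  }
  w <- Matrix::drop0(w)
  rel$weights <- methods::as(methods::as(w, "generalMatrix"), "CsparseMatrix")
  rel$norm_adjacency <- normalize_adjacency(rel$weights)
  graph$relations[[key]] <- rel
  graph
}

#' Rank-based area under the ROC curve
#'
#' Each trial contributes one positive (the true target, at rank `r`) and
#' `n - 1` negatives; the probability that the positive outranks a random
#' negative is `(n - r) / (n - 1)` (the Mann-Whitney statistic), and the AUC
#' is its average over trials.
#'
#' @param ranks Integer ranks achieved by the true targets.
#' @param n_candidates Number of candidates per trial.
#' @return AUC in `[0, 1]`.
#' @export
rank_based_auc <- function(ranks, n_candidates) {
  check_ranks(ranks, n_candidates)
  mean((n_candidates - ranks) / (n_candidates - 1))
}

#' ROC points from a set of trial ranks
#'
#' At cutoff `r` (top-`r` predictions called positive) the true positive rate
#' is the fraction of trials whose true target ranks within the top `r`, and
#' the false positive rate is the mean fraction of the `n - 1` negatives
#' called positive, `(r - [rank <= r]) / (n - 1)`.  The trapezoidal area
#' under these points equals [rank_based_auc()].
#'
#' @inheritParams rank_based_auc
#' @return Data frame with columns `fpr`, `tpr`, from (0, 0) to (1, 1).
#' @export
rank_roc_points <- function(ranks, n_candidates) {
  check_ranks(ranks, n_candidates)
  r <- 0:n_candidates
  tpr <- vapply(r, function(cut) mean(ranks <= cut), numeric(1))
  fpr <- vapply(r, function(cut) mean((cut - (ranks <= cut)) / (n_candidates - 1)),
                numeric(1))
  data.frame(fpr = fpr, tpr = tpr)
}

#' Normalized mean rank of the true targets
#'
#' Mean achieved rank divided by the number of candidates (lower is better),
#' with the standard deviation of the normalized ranks.
#'
#' @inheritParams rank_based_auc
#' @return List with elements `mean` and `sd`.
#' @export
normalized_mean_rank <- function(ranks, n_candidates) {
  check_ranks(ranks, n_candidates)
  list(mean = mean(ranks) / n_candidates,
       sd = stats::sd(ranks / n_candidates))
}

check_ranks <- function(ranks, n_candidates) {
  if (length(ranks) == 0) stop("no trials: the rank list is empty")
  if (n_candidates < 2) stop("n_candidates must be at least 2")
  if (any(ranks < 1 | ranks > n_candidates))
    stop(sprintf("ranks must lie in [1, %d]", n_candidates))
  invisible(TRUE)
}

#' @export
print.netprio_benchmark <- function(x, ...) {
  cat(sprintf("<netprio_benchmark> %d trials, %d candidates each\n",
              nrow(x$trials), x$n_candidates))
  cat(sprintf("  AUC                  %.4f\n", x$auc))
  cat(sprintf("  normalized mean rank %.4f +/- %.4f\n",
              x$normalized_mean_rank,
              ifelse(is.na(x$rank_std), 0, x$rank_std)))
  cat(sprintf("  rank 1 achieved in   %d/%d trials\n",
              sum(x$trials$rank == 1), nrow(x$trials)))
  invisible(x)
}
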
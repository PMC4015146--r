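test_that("path enumeration finds exactly the simple meta-graph paths", {
  # chain Q-A-T plus direct relation Q-T: two paths in lexicographic order
  g <- meta_only_graph(rbind(c("D1", "D2"), c("D2", "D3"), c("D1", "D3")), 3)
  paths <- enumerate_paths(g, "D1", "D3")
  expect_equal(paths, list(c("D1", "D2", "D3"), c("D1", "D3")))
  # single edge: one path
  g2 <- meta_only_graph(rbind(c("D1", "D2")), 2)
  expect_equal(enumerate_paths(g2, "D1", "D2"), list(c("D1", "D2")))
  # a 5-domain layout with exactly three query-target paths
  g3 <- meta_only_graph(rbind(c("D1", "D5"), c("D1", "D2"), c("D2", "D5"),
                              c("D1", "D3"), c("D3", "D4"), c("D4", "D5")), 5)
  expect_length(enumerate_paths(g3, "D1", "D5"), 3)
  # disconnected networks are an error
  g4 <- meta_only_graph(rbind(c("D1", "D2")), 3)
  expect_error(enumerate_paths(g4, "D1", "D3"), "disconnected")
  expect_error(enumerate_paths(g, "D1", "D1"), "distinct")
})

test_that("path enumeration agrees with the igraph all-simple-paths oracle", {
  set.seed(91)
  tried <- 0
  while (tried < 60) {
    nd <- sample(3:6, 1)
    edges <- random_meta_edges(nd, p = runif(1, 0.3, 0.8))
    if (nrow(edges) == 0) next
    tried <- tried + 1
    g <- meta_only_graph(edges, nd)
    ig <- igraph::graph_from_edgelist(edges, directed = FALSE)
    from <- "D1"; to <- paste0("D", nd)
    oracle <- tryCatch(
      lapply(igraph::all_simple_paths(ig, from, to),
             function(p) igraph::V(ig)$name[p]),
      error = function(e) list())
    oracle <- oracle[order(vapply(oracle, paste, character(1), collapse = "\x01"))]
    if (length(oracle) == 0) {
      expect_error(enumerate_paths(g, from, to), "disconnected")
    } else {
      expect_equal(enumerate_paths(g, from, to), oracle)
    }
  }
})

test_that("a length-2 path projects the query state directly", {
  g <- tiny_chain_graph()
  params <- propagation_params(alpha = 0.5, gamma = 1, method = "closed_form")
  xq <- propagate_within(g$domains$A,
                         normalize_prior(init_state(g$domains$A, "a1")), params)
  res <- propagate_along_path(g, c("A", "B"), xq, params)
  expect_equal(res$penultimate_state, xq)
  S <- relation_matrix(g, from = "A", to = "B")
  expect_equal(unname(res$projected), as.numeric(S %*% as.numeric(xq)))
})

test_that("a signal-free route yields an all-zero projection", {
  da <- domain_network("A", c("a1", "a2"),
                       data.frame(from = "a1", to = "a2", weight = 1))
  db <- domain_network("B", c("b1", "b2"))
  dc <- domain_network("C", c("c1", "c2"))
  # relation A~B exists but carries no arcs; B~C has one
  rab <- relation_network(da, db, NULL)
  rbc <- relation_network(db, dc, data.frame(from = "b1", to = "c1", weight = 1))
  g <- global_graph(list(da, db, dc), list(rab, rbc))
  params <- propagation_params(gamma = 0.5)
  xq <- propagate_within(da, normalize_prior(init_state(da, "a1")), params)
  res <- propagate_along_path(g, c("A", "B", "C"), xq, params)
  expect_equal(unname(res$penultimate_state), c(0, 0))
  expect_equal(unname(res$projected), c(0, 0))
})

test_that("path propagation matches an independent scalar-loop recomputation", {
  g <- tiny_chain_graph()
  params <- propagation_params(alpha = 0.8, gamma = 0.5, method = "closed_form")
  x0 <- normalize_prior(init_state(g$domains$A, "a1"))
  xq <- propagate_within(g$domains$A, x0, params)
  res <- propagate_along_path(g, c("A", "B", "C"), xq, params)

  # oracle: dense base-R arithmetic, no package propagation calls
  prop <- function(W, x0, a) {
    M <- normalize_oracle(W)
    as.numeric((1 - a) * solve(diag(nrow(W)) - a * M, x0))
  }
  xq_o <- prop(as.matrix(g$domains$A$weights), as.numeric(x0), 0.8)
  Wab <- as.matrix(find_relation(g, "A", "B")$weights) # rows A, cols B
  state_b <- numeric(4)
  for (k in 1:4) {
    nb <- which(Wab[, k] != 0)
    state_b[k] <- if (length(nb)) mean(xq_o[nb]) else 0
  }
  ord <- order(state_b, seq_along(state_b))
  state_b[ord[seq_len(ceiling(4 * 0.5))]] <- 0
  state_b <- state_b / sum(state_b)
  xb_o <- prop(as.matrix(g$domains$B$weights), state_b, 0.8)
  Sbc <- normalize_oracle(as.matrix(find_relation(g, "B", "C")$weights))
  proj_o <- as.numeric(t(Sbc) %*% xb_o) # rows C after transpose

  expect_equal(unname(res$penultimate_state), xb_o, tolerance = 1e-10)
  expect_equal(unname(res$projected), proj_o, tolerance = 1e-10)
})

test_that("correlation scoring follows the textbook Pearson formula", {
  mk <- function(v) list(path = c("Q", "T"), penultimate_state = NULL,
                         projected = v)
  # proportional vectors correlate perfectly
  expect_equal(score_correlation(list(mk(c(0.2, 0.4, 0.8))), c(0.1, 0.2, 0.4)), 1)
  # all-zero projections carry no evidence
  expect_equal(score_correlation(list(mk(c(0, 0, 0))), c(0.3, 0.1, 0.2)), 0)
  expect_equal(score_correlation(list(mk(c(1, 2, 3))), c(0.5, 0.5, 0.5)), 0)
  # two paths, concatenated 6-point correlation; frozen value computed with
  # the Sigma-formulas by hand and cross-checked against stats::cor
  two <- list(mk(c(0, 1, 2)), mk(c(0, 2, 4)))
  s <- score_correlation(two, c(0, 1, 2))
  expect_equal(s, 0.8846517369, tolerance = 1e-9)
  expect_equal(s, stats::cor(c(0, 1, 2, 0, 2, 4), c(0, 1, 2, 0, 1, 2)),
               tolerance = 1e-12)
})

test_that("prioritization returns a complete, sorted, tie-stable ranking", {
  g <- random_two_net_graph(n_q = 12, n_t = 9, seed = 101)
  params <- propagation_params(gamma = 1)
  rk <- prioritize(g, g$domains$q$nodes[1:2], "q", "t", params)
  expect_equal(nrow(rk), 9)
  expect_equal(rk$rank, 1:9)
  expect_setequal(rk$entity, g$domains$t$nodes)
  expect_true(all(diff(rk$score) <= 1e-14))
  expect_true(all(rk$score >= -1 - 1e-12 & rk$score <= 1 + 1e-12))
  expect_error(prioritize(g, character(0), "q", "t", params), "empty")
})

test_that("automorphic target nodes score equally and order by index", {
  dq <- domain_network("Q", c("q1", "q2"),
                       data.frame(from = "q1", to = "q2", weight = 1))
  dt <- domain_network("T", c("t1", "t2", "t3"),
                       data.frame(from = c("t1", "t2"), to = c("t3", "t3"),
                                  weight = c(0.5, 0.5)))
  # t1 and t2 are swapped by an automorphism fixing the query side
  rel <- relation_network(dq, dt,
                          data.frame(from = c("q1", "q1"), to = c("t1", "t2"),
                                     weight = c(1, 1)))
  g <- global_graph(list(dq, dt), list(rel))
  rk <- prioritize(g, "q1", "Q", "T", propagation_params(gamma = 1))
  s <- attr(rk, "scores")
  expect_equal(s[["t1"]], s[["t2"]], tolerance = 1e-12)
  expect_equal(match(c("t1", "t2"), rk$entity)[1] + 1,
               match(c("t1", "t2"), rk$entity)[2])
  expect_true(match("t1", rk$entity) < match("t2", rk$entity))
})

test_that("zero-noise planted association is recovered at rank 1 (chain)", {
  for (s in c(5, 17)) {
    spec <- fixture_spec(n_domains = 3, sizes = c(60, 50, 70),
                         intra_density = 0.1, inter_density = 0.05,
                         planted_pairs = 1, n_helpers = 4, n_relays = 3,
                         noise = 0, seed = s)
    fix <- generate_hetnet(spec)
    rk <- prioritize(fix$graph, fix$pairs$query_entity[1], "d1", "d3",
                     propagation_params(gamma = 0.1))
    expect_equal(rk$entity[1], fix$pairs$true_target[1])
  }
})

test_that("the general pipeline reduces to the 2-network special case", {
  # independent dense implementation of the 2-network enumeration-correlation
  # scheme, written against base R only
  special_case_ranking <- function(Wq, Wt, R, q_idx, alpha) {
    Mq <- normalize_oracle(Wq); Mt <- normalize_oracle(Wt)
    S <- t(normalize_oracle(R)) # rows target, cols query
    x0 <- numeric(nrow(Wq)); x0[q_idx] <- 1 / length(q_idx)
    xq <- as.numeric((1 - alpha) * solve(diag(nrow(Wq)) - alpha * Mq, x0))
    xbar <- as.numeric(S %*% xq)
    Ft <- (1 - alpha) * solve(diag(nrow(Wt)) - alpha * Mt)
    s <- vapply(seq_len(nrow(Wt)), function(e) {
      te <- Ft[, e]
      if (stats::sd(xbar) == 0 || stats::sd(te) == 0) 0 else stats::cor(xbar, te)
    }, numeric(1))
    order(-s, seq_along(s))
  }
  set.seed(111)
  params <- propagation_params(method = "closed_form", gamma = 1)
  for (i in 1:12) {
    n_q <- sample(6:18, 1); n_t <- sample(5:15, 1)
    g <- random_two_net_graph(n_q, n_t, seed = 1000 + i)
    q_idx <- sort(sample(n_q, sample(1:3, 1)))
    rk <- prioritize(g, g$domains$q$nodes[q_idx], "q", "t", params)
    oracle_ord <- special_case_ranking(as.matrix(g$domains$q$weights),
                                       as.matrix(g$domains$t$weights),
                                       as.matrix(find_relation(g, "q", "t")$weights),
                                       q_idx, 0.9)
    expect_equal(rk$entity, g$domains$t$nodes[oracle_ord])
  }
})

test_that("rankings are invariant under node-order permutation", {
  spec <- fixture_spec(n_domains = 3, sizes = c(30, 25, 20),
                       intra_density = 0.15, inter_density = 0.1,
                       planted_pairs = 1, seed = 13)
  fix <- generate_hetnet(spec)
  params <- propagation_params(gamma = 0.3, method = "closed_form")
  q <- fix$pairs$query_entity[1]
  base <- attr(prioritize(fix$graph, q, "d1", "d3", params), "scores")
  set.seed(14)
  for (dom in c("d1", "d2", "d3")) {
    g2 <- permute_domain(fix$graph, dom)
    s2 <- attr(prioritize(g2, q, "d1", "d3", params), "scores")
    expect_lt(max(abs(s2[names(base)] - base)), 1e-10)
  }
})

test_that("a 4-domain grid prioritization completes with a full ranking", {
  spec <- fixture_spec(n_domains = 4, sizes = 200,
                       topology = rbind(c(1, 2), c(2, 4), c(1, 3), c(3, 4), c(1, 4)),
                       intra_density = 0.03, inter_density = 0.02,
                       planted_pairs = 2, seed = 19)
  fix <- generate_hetnet(spec)
  rk <- prioritize(fix$graph, fix$pairs$query_entity[1], "d1", "d4",
                   propagation_params(gamma = 0.1))
  expect_length(attr(rk, "paths"), 3)
  expect_equal(nrow(rk), 200)
  expect_equal(rk$rank, 1:200)
})
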
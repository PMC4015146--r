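#' Read a weighted edge list
#'
#' Tab-separated file with two node-id columns and one numeric weight
#' column; each undirected pair listed once.  Lines starting with `#` are
#' comments.  A header line is detected automatically (third field not
#' numeric).
#'
#' @param path File path.
#' @return Data frame with columns `from`, `to`, `weight`.
#' @export
read_edgelist <- function(path) {
  if (!file.exists(path)) stop(sprintf("edge-list file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(data.frame(from = character(0), to = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  has_header <- length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3])))
  df <- utils::read.table(text = lines, sep = "\t", header = has_header,
                          colClasses = c("character", "character", "numeric"),
                          col.names = c("from", "to", "weight"),
                          comment.char = "", stringsAsFactors = FALSE)
  names(df) <- c("from", "to", "weight")
  df
}

#' Write a weighted edge list
#'
#' @param edges Data frame with columns `from`, `to`, `weight`.
#' @param path Output path.
#' @param header Write a header line (default `TRUE`).
#' @param digits Significant digits for the weights; the default 17 makes
#'   write/read round-trips bit-exact for doubles.
#' @export
write_edgelist <- function(edges, path, header = TRUE, digits = 17) {
  df <- data.frame(from = edges$from, to = edges$to,
                   weight = sprintf("%.*g", digits, edges$weight))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

sparse_to_edges <- function(m, undirected) {
  m <- methods::as(methods::as(m, "generalMatrix"), "TsparseMatrix")
  i <- m@i + 1L; j <- m@j + 1L; x <- m@x
  if (undirected) {
    keep <- i <= j
    i <- i[keep]; j <- j[keep]; x <- x[keep]
  }
  data.frame(from = rownames(m)[i], to = colnames(m)[j], weight = x,
             stringsAsFactors = FALSE)
}

#' Write a global graph as plain-text files
#'
#' Creates `<id>.nodes.txt` (one node id per line, canonical order) and
#' `<id>.edges.tsv` per network, plus `<a>__<b>.edges.tsv` per relation,
#' under `dir`.  [read_global_graph()] restores an identical graph.
#'
#' @param graph A `global_graph`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_global_graph <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in graph$domains) {
    writeLines(d$nodes, file.path(dir, paste0(d$id, ".nodes.txt")))
    write_edgelist(sparse_to_edges(d$weights, undirected = TRUE),
                   file.path(dir, paste0(d$id, ".edges.tsv")))
  }
  for (r in graph$relations) {
    write_edgelist(sparse_to_edges(r$weights, undirected = FALSE),
                   file.path(dir, paste0(r$source_id, "__", r$target_id,
                                         ".edges.tsv")))
  }
  invisible(dir)
}

#' Read a global graph written by [write_global_graph()]
#'
#' @param dir Directory holding `*.nodes.txt` and `*.edges.tsv` files.
#' @return A `global_graph`.
#' @export
read_global_graph <- function(dir) {
  node_files <- sort(list.files(dir, pattern = "\\.nodes\\.txt$", full.names = TRUE))
  if (length(node_files) == 0)
    stop(sprintf("no '*.nodes.txt' files found in %s", dir))
  domains <- lapply(node_files, function(f) {
    id <- sub("\\.nodes\\.txt$", "", basename(f))
    domain_network(id, readLines(f),
                   read_edgelist(file.path(dir, paste0(id, ".edges.tsv"))))
  })
  names(domains) <- vapply(domains, `[[`, character(1), "id")
  rel_files <- sort(list.files(dir, pattern = "__.*\\.edges\\.tsv$", full.names = TRUE))
  relations <- lapply(rel_files, function(f) {
    ids <- strsplit(sub("\\.edges\\.tsv$", "", basename(f)), "__", fixed = TRUE)[[1]]
    if (length(ids) != 2 || !all(ids %in% names(domains)))
      stop(sprintf("relation file %s does not name two known networks", basename(f)))
    relation_network(domains[[ids[1]]], domains[[ids[2]]], read_edgelist(f))
  })
  global_graph(domains, relations)
}

#' Load a run configuration
#'
#' YAML file describing a prioritization run: the network and relation
#' files, the query network and query set, the target network, and optional
#' propagation parameters (defaults `alpha = 0.9`, `kappa = 1e-5`,
#' `gamma = 0.00375`).
#'
#' Recognized keys: `networks` (map id -> `{nodes: path, edges: path}`),
#' `relations` (list of `{source, target, edges}`), `query_network`,
#' `target_network`, `query_set` (list of entity ids, or `{file: path}` with
#' one id per line), `params` (`alpha`, `kappa`, `gamma`, `max_iters`,
#' `method`), `output`, `log_level`.
#'
#' @param path YAML config path.
#' @return List of class `run_config` with elements `graph_files`,
#'   `query_network`, `target_network`, `query_set`, `params`, `output`,
#'   `log_level`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  known <- c("networks", "relations", "query_network", "target_network",
             "query_set", "params", "output", "log_level")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop(sprintf("unknown config key '%s'", unknown[1]))
  for (req in c("networks", "query_network", "target_network", "query_set"))
    if (is.null(cfg[[req]])) stop(sprintf("config is missing required key '%s'", req))
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (grepl("^/", p)) p else file.path(base, p)
  net_ids <- names(cfg$networks)
  for (id in net_ids) {
    for (part in c("nodes", "edges")) {
      f <- cfg$networks[[id]][[part]]
      if (is.null(f)) stop(sprintf("network '%s' is missing its '%s' file", id, part))
      cfg$networks[[id]][[part]] <- resolve(f)
      if (!file.exists(cfg$networks[[id]][[part]]))
        stop(sprintf("file for network '%s' does not exist: %s", id, f))
    }
  }
  for (k in seq_along(cfg$relations)) {
    r <- cfg$relations[[k]]
    if (is.null(r$source) || is.null(r$target) || is.null(r$edges))
      stop("each relation needs 'source', 'target' and 'edges'")
    if (!r$source %in% net_ids || !r$target %in% net_ids)
      stop(sprintf("relation %s~%s references an undeclared network",
                   r$source, r$target))
    cfg$relations[[k]]$edges <- resolve(r$edges)
    if (!file.exists(cfg$relations[[k]]$edges))
      stop(sprintf("relation file does not exist: %s", r$edges))
  }
  if (!cfg$query_network %in% net_ids)
    stop(sprintf("query_network '%s' is not a declared network", cfg$query_network))
  if (!cfg$target_network %in% net_ids)
    stop(sprintf("target_network '%s' is not a declared network", cfg$target_network))
  qs <- cfg$query_set
  if (is.list(qs) && !is.null(qs$file)) {
    f <- resolve(qs$file)
    if (!file.exists(f)) stop(sprintf("query_set file does not exist: %s", qs$file))
    qs <- readLines(f)
    qs <- trimws(qs[nzchar(trimws(qs))])
  }
  qs <- as.character(unlist(qs))
  if (length(qs) == 0) stop("query_set is empty")
  p <- cfg$params
  if (!is.null(p)) {
    unknown <- setdiff(names(p), c("alpha", "kappa", "gamma", "max_iters", "method"))
    if (length(unknown)) stop(sprintf("unknown params key '%s'", unknown[1]))
  }
  if (!is.null(p$alpha) && p$alpha >= 1)
    stop("alpha must be < 1: alpha = 1 makes the closed-form system I - alpha*M singular")
  params <- propagation_params(
    alpha = p$alpha %||% 0.9, kappa = p$kappa %||% 1e-5,
    gamma = p$gamma %||% 0.00375, max_iters = p$max_iters %||% 1000L,
    method = p$method %||% "iterative")
  structure(list(networks = cfg$networks, relations = cfg$relations,
                 query_network = cfg$query_network,
                 target_network = cfg$target_network,
                 query_set = qs, params = params,
                 output = if (is.null(cfg$output)) NULL else resolve(cfg$output),
                 log_level = cfg$log_level %||% "info"),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the global graph described by a run configuration
#'
#' @param config A `run_config` from [load_config()].
#' @return A `global_graph`.
#' @export
config_graph <- function(config) {
  domains <- lapply(names(config$networks), function(id) {
    spec <- config$networks[[id]]
    domain_network(id, readLines(spec$nodes), read_edgelist(spec$edges))
  })
  names(domains) <- names(config$networks)
  relations <- lapply(config$relations, function(r)
    relation_network(domains[[r$source]], domains[[r$target]],
                     read_edgelist(r$edges)))
  global_graph(domains, relations)
}

#' Write a ranking as TSV
#'
#' Columns `rank`, `entity_id`, `score`; scores printed with 8 significant
#' digits so reruns are diff-stable.
#'
#' @param ranking A `netprio_ranking` from [prioritize()].
#' @param path Output path.
#' @export
write_ranking <- function(ranking, path) {
  df <- data.frame(rank = ranking$rank, entity_id = ranking$entity,
                   score = sprintf("%.8g", ranking$score))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a benchmark report
#'
#' Per-trial ranks as TSV plus a plain-text summary block (AUC, normalized
#' mean rank +/- std).
#'
#' @param report A `netprio_benchmark` from [run_loo()].
#' @param path Output TSV path; the summary goes to `<path>.summary.txt`.
#' @export
write_benchmark <- function(report, path) {
  utils::write.table(report$trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  summary_path <- paste0(path, ".summary.txt")
  writeLines(c(
    sprintf("trials\t%d", nrow(report$trials)),
    sprintf("candidates\t%d", report$n_candidates),
    sprintf("auc\t%.8g", report$auc),
    sprintf("normalized_mean_rank\t%.8g", report$normalized_mean_rank),
    sprintf("rank_std\t%.8g", ifelse(is.na(report$rank_std), 0, report$rank_std))
  ), summary_path)
  invisible(path)
}
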
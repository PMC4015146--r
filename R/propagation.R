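#' Propagation parameters
#'
#' Bundles the tunable constants of the propagation pipeline.
#'
#' @param alpha Prior-importance weight in `[0, 1]`.  The within-network
#'   fixed point is `x = alpha * M x + (1 - alpha) * x0`; larger values let
#'   the network topology dominate the prior.  Default 0.9.
#' @param kappa Stopping tolerance for the iterative solver: iteration halts
#'   once the maximum absolute change between successive iterates drops to
#'   `kappa` or below.  Default `1e-5`.
#' @param gamma Survival fraction of the between-network noise threshold in
#'   `(0, 1]`: after propagating values into an intermediate network the
#'   `ceiling(n * (1 - gamma))` lowest node values are zeroed.  Default
#'   0.00375 (tuned for networks of several thousand nodes; raise it on
#'   small graphs so a useful number of nodes survive).
#' @param max_iters Iteration cap for the iterative solver; exceeding it is
#'   an error, not a silent return.  Default 1000.
#' @param method Within-network solver, `"iterative"` or `"closed_form"`.
#' @return A list of class `propagation_params`.
#' @export
propagation_params <- function(alpha = 0.9, kappa = 1e-5, gamma = 0.00375,
                               max_iters = 1000L, method = c("iterative", "closed_form")) {
  method <- match.arg(method)
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha < 0 || alpha > 1)
    stop("alpha must be a number in [0, 1]")
  if (!is.numeric(kappa) || length(kappa) != 1 || is.na(kappa) || kappa <= 0)
    stop("kappa must be > 0")
  if (!is.numeric(gamma) || length(gamma) != 1 || is.na(gamma) ||
      gamma <= 0 || gamma > 1)
    stop("gamma must lie in (0, 1]")
  if (!is.numeric(max_iters) || length(max_iters) != 1 || max_iters < 1)
    stop("max_iters must be >= 1")
  structure(list(alpha = alpha, kappa = kappa, gamma = gamma,
                 max_iters = as.integer(max_iters), method = method),
            class = "propagation_params")
}

#' Normalize a prior state to unit total
#'
#' The nonzero entries (the prior information set) are divided by their sum
#' so that the state totals 1; zero entries and the support are unchanged.
#'
#' @param state Nonnegative numeric state vector.
#' @return State vector summing to 1.
#' @export
normalize_prior <- function(state) {
  total <- sum(state)
  if (total == 0) stop("empty prior set: all state values are zero")
  state / total
}

#' Flow propagation within a network
#'
#' Diffuses a prior state over a network's degree-normalized adjacency `M`.
#' The closed form returns `(1 - alpha) * solve(I - alpha * M) %*% x0`; the
#' iterative scheme repeats `x <- alpha * M x + (1 - alpha) * x0` from
#' `x = x0` until the largest componentwise change is at most
#' `params$kappa`.  Because the symmetric normalization bounds the spectral
#' radius of `M` by 1, successive updates contract at rate `alpha` and the
#' two solvers agree to within a small multiple of `kappa`.
#'
#' @param network A `domain_network`.
#' @param prior Numeric prior state aligned to the network's node order
#'   (normalize with [normalize_prior()] first when it represents a seed set).
#' @param params A `propagation_params` object.
#' @param method Override of `params$method`.
#' @return The propagated state, with attributes `iterations` and
#'   `residuals` (L2 change per iteration) when computed iteratively.
#' @export
propagate_within <- function(network, prior, params = propagation_params(),
                             method = params$method) {
  method <- match.arg(method, c("iterative", "closed_form"))
  stopifnot(length(prior) == length(network$nodes))
  alpha <- params$alpha
  M <- network$norm_adjacency
  x0 <- as.numeric(prior)
  if (alpha == 0) {
    out <- x0
  } else if (method == "closed_form") {
    if (alpha == 1)
      stop("closed-form propagation requires alpha < 1: I - alpha*M is singular when alpha = 1 on a normalized component")
    A <- Matrix::Diagonal(length(x0)) - alpha * M
    out <- as.numeric(Matrix::solve(A, x0)) * (1 - alpha)
  } else {
    x <- x0
    residuals <- numeric(0)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      x_new <- alpha * as.numeric(M %*% x) + (1 - alpha) * x0
      delta <- x_new - x
      residuals[iter] <- sqrt(sum(delta^2))
      x <- x_new
      if (max(abs(delta)) <= params$kappa) break
      if (iter >= params$max_iters)
        stop(sprintf(
          "propagation in '%s' did not converge in %d iterations (last max change %.3g > kappa = %.3g)",
          network$id, iter, max(abs(delta)), params$kappa))
    }
    out <- x
    attr(out, "iterations") <- iter
    attr(out, "residuals") <- residuals
  }
  names(out)[seq_along(network$nodes)] <- network$nodes
  out
}

#' Propagate a state across a bipartite relation
#'
#' Each node of the destination network receives the unweighted arithmetic
#' mean of the state values of its cross-network neighbors (the nodes it is
#' linked to by the relation); destination nodes with no cross-network
#' neighbors receive 0.  Arc weights do not enter this step; they act only
#' through the normalized relation matrix used at the correlation stage.
#'
#' @param source_state Numeric state on the source-side network.
#' @param relation A `relation_network` joining the two networks.
#' @param from,to Ids of the source and destination networks.
#' @return Numeric state over the destination network's nodes.
#' @export
propagate_between <- function(source_state, relation, from, to) {
  ok <- (relation$source_id == from && relation$target_id == to) ||
        (relation$source_id == to && relation$target_id == from)
  if (!ok)
    stop(sprintf("relation %s~%s does not connect networks '%s' and '%s'",
                 relation$source_id, relation$target_id, from, to))
  w <- if (relation$source_id == from) Matrix::t(relation$weights) else relation$weights
  pattern <- w
  pattern@x <- rep(1, length(pattern@x))
  counts <- Matrix::rowSums(pattern)
  out <- as.numeric(pattern %*% as.numeric(source_state))
  out <- ifelse(counts > 0, out / pmax(counts, 1), 0)
  names(out) <- rownames(w)
  out
}

#' Zero out the lowest node values
#'
#' After between-network propagation, exactly `ceiling(n * (1 - gamma))` of
#' the `n` node values -- the lowest ones -- are set to zero to stop noise
#' from diffusing further; the remaining values are unchanged.  Ties are
#' broken by canonical node index: among equal values the lower index is
#' zeroed first.
#'
#' @param state Numeric state vector.
#' @param gamma Survival fraction in `(0, 1]`.
#' @return Thresholded state vector.
#' @export
apply_gamma_threshold <- function(state, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1 || is.na(gamma) ||
      gamma <= 0 || gamma > 1)
    stop("gamma must lie in (0, 1]")
  n <- length(state)
  k <- ceiling(n * (1 - gamma))
  if (k > 0) {
    ord <- order(as.numeric(state), seq_len(n))
    state[ord[seq_len(k)]] <- 0
  }
  state
}
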
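#' Degree-normalize a nonnegative adjacency matrix
#'
#' Computes the symmetric degree normalization `D1 %*% N %*% D2`, where `D1`
#' and `D2` are diagonal matrices holding the inverse square roots of the row
#' and column sums of `N`.  Entry `(j, k)` of the result is
#' `N[j, k] / sqrt(rowSums(N)[j] * colSums(N)[k])`.  Rows or columns whose sum
#' is zero (isolated nodes) are mapped to zero rather than `NaN`, so isolated
#' nodes neither emit nor receive flow.
#'
#' For a symmetric input the output is symmetric and all its eigenvalues lie
#' in `[-1, 1]`, which guarantees convergence of the iterative flow
#' propagation.  The same formula applies unchanged to rectangular bipartite
#' adjacencies.
#'
#' @param raw A base matrix or `Matrix` sparse matrix with nonnegative finite
#'   entries.  Rows and columns may index different node sets.
#' @return A `dgCMatrix` of the same dimension with normalized weights.
#' @examples
#' normalize_adjacency(matrix(c(1, 0, 1, 1), 2))
#' @export
normalize_adjacency <- function(raw) {
  raw <- methods::as(methods::as(Matrix::Matrix(raw, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  bad <- which(!is.finite(raw@x) | raw@x < 0)
  if (length(bad)) {
    b <- bad[1]
    row <- raw@i[b] + 1L
    col <- findInterval(b, raw@p, left.open = TRUE)
    stop(sprintf("adjacency entry at row %d, column %d is negative or non-finite",
                 row, col))
  }
  rs <- Matrix::rowSums(raw)
  cs <- Matrix::colSums(raw)
  d1 <- ifelse(rs > 0, 1 / sqrt(rs), 0)
  d2 <- ifelse(cs > 0, 1 / sqrt(cs), 0)
  out <- Matrix::Diagonal(x = d1) %*% raw %*% Matrix::Diagonal(x = d2)
  out <- methods::as(methods::as(out, "generalMatrix"), "CsparseMatrix")
  dimnames(out) <- dimnames(raw)
  out
}
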
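#' QR decomposition by modified Gram-Schmidt
#'
#' Factors a square full-rank matrix as `A = Q R` with `Q` orthogonal and
#' `R` upper triangular with strictly positive diagonal.  Modified
#' Gram-Schmidt is used for numerical stability; a pivot whose
#' post-projection norm falls below `tol` times the largest column norm is
#' declared rank deficient.  The Gram-Schmidt pivot is a column norm and
#' hence positive by construction; a defensive sign flip of the
#' (Q column, R row) pair enforces the convention regardless.
#'
#' @param A square numeric matrix.
#' @param tol relative rank tolerance (default `1e-12`).
#' @return list with orthogonal `Q` and upper-triangular `R`.
#' @export
gram_schmidt_qr <- function(A, tol = 1e-12) {
  A <- as.matrix(A)
  n <- ncol(A)
  if (nrow(A) != n) stop("`A` must be square")
  scale <- max(sqrt(colSums(A^2)))
  if (scale == 0) stop("rank deficiency at column 1")
  Q <- matrix(0, n, n)
  R <- matrix(0, n, n)
  for (cc in seq_len(n)) {
    v <- A[, cc]
    for (p in seq_len(cc - 1L)) {
      R[p, cc] <- sum(Q[, p] * v)
      v <- v - R[p, cc] * Q[, p]
    }
    nv <- sqrt(sum(v^2))
    if (nv < tol * scale)
      stop(sprintf("rank deficiency at column %d", cc))
    R[cc, cc] <- nv
    Q[, cc] <- v / nv
    if (R[cc, cc] < 0) {           # unreachable for Gram-Schmidt pivots;
      Q[, cc] <- -Q[, cc]          # kept to make the sign convention explicit
      R[cc, ] <- -R[cc, ]
    }
  }
  list(Q = Q, R = R)
}

#' LQ decomposition of a pattern-conforming loadings matrix
#'
#' Computes `Gamma = L Q` where the leading `m x m` block of `L` is lower
#' triangular with strictly positive diagonal and `Q` is orthogonal.  The
#' construction transposes the loadings, QR-decomposes the square leading
#' part by Gram-Schmidt (`Gamma_1' = Qg R1`), forms `R2 = Qg' Gamma_2'` and
#' returns `L = [R1 | R2]'` and `Q = Qg'`, so that the identity
#' `Gamma = L Q` holds exactly.
#'
#' @param values `K x m` loadings matrix conforming to `pattern`.
#' @param pattern a validated [loadings_pattern].
#' @param tol rank tolerance passed to [gram_schmidt_qr()].
#' @return An object of class `lq_pair`: list with `L` (`K x m`, rows in
#'   `outcome_order`), `Q` (`m x m`) and `outcome_order`.
#' @export
lq_decompose <- function(values, pattern, tol = 1e-12) {
  parts <- partition_loadings(values, pattern)
  gs <- gram_schmidt_qr(parts$A1, tol = tol)
  R <- cbind(gs$R, if (ncol(parts$A2) > 0) t(gs$Q) %*% parts$A2)
  structure(list(L = t(R), Q = t(gs$Q),
                 outcome_order = parts$outcome_order),
            class = "lq_pair")
}

#' Identified loadings and factors
#'
#' Maps raw `(Gamma, F)` to the rotation-identified pair `(L, F~)` with
#' `F~_ij = Q F_ij`, so that `L F~_ij = Gamma F_ij` (up to floating point)
#' for every unit-time cell.
#'
#' @param values `K x m` loadings matrix.
#' @param pattern a validated [loadings_pattern].
#' @param factors `I x J x m` array of factor values.
#' @return list with `L`, `Q`, and `f_tilde` (`I x J x m` array).
#' @export
identified_quantities <- function(values, pattern, factors) {
  lq <- lq_decompose(values, pattern)
  factors <- as.array(factors)
  d <- dim(factors)
  if (length(d) != 3L || d[3] != ncol(lq$L))
    stop("`factors` must be I x J x m with m matching the loadings")
  fmat <- matrix(factors, nrow = d[1] * d[2], ncol = d[3])
  ft <- array(fmat %*% t(lq$Q), dim = d)
  list(L = lq$L, Q = lq$Q, f_tilde = ft)
}
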
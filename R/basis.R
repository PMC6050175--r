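#' Nonlinear pairwise regression basis
#'
#' Each GMDH unit regresses the class on `Nn = 7` nonlinear functions of a
#' predictor pair `(xi, xj)` with inputs in \[0,1\]:
#' \deqn{a_1,\; a_2 (1+x_i)^{a_3},\; a_4 x_j^{a_5},\; a_6 \sin(a_7 x_i + a_8 x_j),}
#' \deqn{a_9\, x_i (1+x_j)^{a_{10}},\; a_{11}\log_2(1+(1+x_i)^{a_{12}}),\;
#'       a_{13}\log_2(1+(1+x_j)^{a_{14}})}
#' Amplitude coefficients (a1, a2, a4, a6, a7, a8, a9, a11, a13) are bounded
#' in \[-5,5\] and exponent coefficients (a3, a5, a10, a12, a14) in
#' \[0.1,3\], which guarantees every basis entry is finite on \[0,1\] inputs.
#'
#' @param xi,xj numeric vectors in \[0,1\], same length N.
#' @param a numeric length-14 coefficient vector within the bounds of
#'   [basis_bounds()].
#' @return `Nn x N` numeric matrix (rows = basis functions, columns =
#'   samples).
#' @export
basis_matrix <- function(xi, xj, a) {
  stopifnot(length(xi) == length(xj), length(a) == 14L, all(is.finite(a)))
  N <- length(xi)
  rbind(
    rep(a[1], N),
    a[2] * (1 + xi)^a[3],
    a[4] * xj^a[5],
    a[6] * sin(a[7] * xi + a[8] * xj),
    a[9] * xi * (1 + xj)^a[10],
    a[11] * log2(1 + (1 + xi)^a[12]),
    a[13] * log2(1 + (1 + xj)^a[14])
  )
}

#' Coefficient box for the pairwise basis
#'
#' @return List with `lower` and `upper` length-14 vectors: amplitudes in
#'   \[-5,5\], exponents in \[0.1,3\].
#' @export
basis_bounds <- function() {
  exps <- c(3L, 5L, 10L, 12L, 14L)
  lower <- rep(-5, 14); upper <- rep(5, 14)
  lower[exps] <- 0.1; upper[exps] <- 3
  list(lower = lower, upper = upper)
}

N_BASIS <- 7L

#' Regularized least squares (ridge) solve
#'
#' Closed-form solution of the ridge problem for the unit weights:
#' `W = (X X' + lambda I)^{-1} X B`, the unique global minimizer of
#' `||X' W - B||^2 + lambda ||W||^2`.
#'
#' @param X `Nn x N` basis matrix (finite entries).
#' @param B length-N response vector (0/1 class labels).
#' @param lambda positive ridge penalty (default 0.1).
#' @return Length-`Nn` weight vector.
#' @export
rls_solve <- function(X, B, lambda = 0.1) {
  X <- as.matrix(X)
  stopifnot(lambda > 0, ncol(X) == length(B))
  if (!all(is.finite(X))) stop("non-finite entries in the basis matrix")
  A <- tcrossprod(X) + lambda * diag(nrow(X))
  drop(solve(A, X %*% B))
}
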
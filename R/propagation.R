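#' Initialize base-encoder weights
#'
#' The base encoder is an affine map \eqn{Z = X W_f + b_f} from initial text
#' features to the embedding space. Weights are drawn
#' \eqn{N(0, 1/\sqrt{d_{in}})}, bias zero.
#'
#' @param d_in Input feature dimensionality.
#' @param d Embedding dimensionality (default 64).
#' @param seed Integer seed for the draw.
#' @return List with matrix `Wf` (`d_in x d`) and vector `bf` (length `d`).
#' @export
init_encoder <- function(d_in, d = 64, seed = 1) {
  set.seed(seed)
  list(Wf = matrix(rnorm(d_in * d, sd = 1 / sqrt(d_in)), d_in, d),
       bf = numeric(d))
}

#' Apply the base encoder
#'
#' @param X Feature matrix (`|V| x d_in`).
#' @param theta Encoder weights: list with `Wf` (`d_in x d`) and `bf`
#'   (length `d`).
#' @return Embedding matrix `Z = X Wf + bf` (`|V| x d`).
#' @export
base_encode <- function(X, theta) {
  if (ncol(X) != nrow(theta$Wf)) {
    abort(sprintf("feature/weight shape mismatch: X is %d x %d but Wf is %d x %d",
                  nrow(X), ncol(X), nrow(theta$Wf), ncol(theta$Wf)))
  }
  Z <- X %*% theta$Wf
  sweep(Z, 2, theta$bf, "+")
}

#' Personalized-PageRank propagation of node embeddings (APPNP)
#'
#' Smooths embeddings over the graph with the approximate personalized-
#' PageRank recurrence
#' \deqn{H^{(0)} = Z, \quad H^{(k)} = (1-\alpha)\,\hat A\, H^{(k-1)} + \alpha Z,}
#' returning \eqn{H = H^{(K)}}. As \eqn{K \to \infty} this converges to the
#' personalized-PageRank fixed point
#' \eqn{\alpha (I - (1-\alpha)\hat A)^{-1} Z}. The operation is linear in `Z`,
#' so gradients flow through all `K` steps via the adjoint recurrence (the
#' same iteration with \eqn{\hat A^\top}).
#'
#' @param Z Embedding matrix (`|V| x d`).
#' @param A_hat Row-stochastic square matrix from [normalized_adjacency()].
#' @param alpha Teleport probability in (0, 1); default 0.1.
#' @param K Number of propagation steps (>= 0); default 10.
#' @return Propagated embedding matrix `H`, same shape as `Z`.
#' @export
appnp <- function(Z, A_hat, alpha = 0.1, K = 10) {
  Z <- as.matrix(Z)
  if (nrow(A_hat) != ncol(A_hat) || nrow(A_hat) != nrow(Z)) {
    abort("A_hat must be square with one row per row of Z")
  }
  if (!(alpha > 0 && alpha < 1)) abort("alpha must be in (0, 1)")
  if (K < 0 || K != round(K)) abort("K must be a non-negative integer")
  rs <- Matrix::rowSums(A_hat)
  if (max(abs(rs - 1)) > 1e-8) {
    abort("A_hat is not row-stochastic (row sums deviate from 1)")
  }
  appnp_raw(Z, A_hat, alpha, K)
}

#' Closed-form APPNP fixed point
#'
#' Dense solve of \eqn{\alpha (I - (1-\alpha)\hat A)^{-1} Z}; intended for
#' small graphs as an independent check of the iterative propagation.
#'
#' @inheritParams appnp
#' @return The limiting embedding matrix.
#' @export
appnp_fixed_point <- function(Z, A_hat, alpha = 0.1) {
  n <- nrow(A_hat)
  M <- diag(n) - (1 - alpha) * as.matrix(A_hat)
  alpha * solve(M, as.matrix(Z))
}
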
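#' Steady-state covariance of a stable linear SDE
#'
#' For the stationary solution of \code{dx = W x dt + D dbeta} with
#' Brownian variance \code{Q}, the covariance \code{P} solves the Lyapunov
#' matrix equation \deqn{W P + P W' + D Q D' = 0,} solved here by
#' vectorization with the Kronecker form
#' \code{vec(P) = -(I (x) W + W (x) I)^{-1} vec(D Q D')}.
#'
#' @param W stable square coupling matrix (all eigenvalue real parts < 0).
#' @param D noise-structure matrix (default identity).
#' @param Q Brownian variance matrix, or a scalar taken as \code{Q = q I}
#'   (default identity).
#' @return Symmetric positive semidefinite covariance matrix.
#' @examples
#' lyapunov_steady_cov(-diag(3))           # = I / 2
#' @export
lyapunov_steady_cov <- function(W, D = NULL, Q = NULL) {
  W <- as.matrix(W)
  n <- nrow(W)
  if (ncol(W) != n) stop("`W` must be square")
  ev <- eigen(W, only.values = TRUE)$values
  if (max(Re(ev)) >= 0)
    stop("`W` is not stable (max real eigenvalue part = ",
         format(max(Re(ev))), "); the stationary covariance does not exist")
  if (is.null(D)) D <- diag(n)
  if (is.null(Q)) Q <- diag(n)
  if (length(Q) == 1L) Q <- diag(as.numeric(Q), n)
  Sigma <- D %*% Q %*% t(D)
  A <- kronecker(diag(n), W) + kronecker(W, diag(n))
  P <- matrix(-solve(A, as.vector(Sigma)), n, n)
  (P + t(P)) / 2
}
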
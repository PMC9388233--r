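# Deflation PCA.  Components are extracted sequentially: each step
# maximizes ||Xhat_i w||^2 over unit w by power iteration on the deflated
# cross-product matrix Xhat_i^T Xhat_i, where
#   Xhat_i = X - sum_{s<i} X w_s w_s^T.
# Eigenvalues are those of the centered X^T X (no 1/n scaling), so the
# score-covariance identity Q[j,k] = (X w_j)^T (X w_k) = lambda_k w_j^T w_k
# holds with these lambdas directly.

.powerIteration <- function(M, Wprev, tol = 1e-13, maxit = 100000L) {
  d <- nrow(M)
  scaleM <- max(abs(M))
  if (!is.finite(scaleM) || scaleM == 0) return(NULL)
  M <- M / scaleM
  project <- function(v) {
    if (ncol(Wprev) > 0L) v <- v - Wprev %*% crossprod(Wprev, v)
    v
  }
  # deterministic start: strongest column of M, orthogonalized; fall back
  # to canonical basis vectors if that direction is degenerate
  v <- project(M[, which.max(colSums(M^2)), drop = FALSE])
  j <- 0L
  while (sqrt(sum(v^2)) < 1e-10 && j < d) {
    j <- j + 1L
    v <- project(diag(d)[, j, drop = FALSE])
  }
  nv <- sqrt(sum(v^2))
  if (nv < 1e-10) return(NULL)
  v <- v / nv
  lam <- 0
  for (it in seq_len(maxit)) {
    u <- project(M %*% v)
    nu <- sqrt(sum(u^2))
    if (nu < 1e-14) return(list(w = v, lambda = 0))
    u <- u / nu
    lam <- as.numeric(crossprod(u, M %*% u))
    res <- sqrt(sum((M %*% u - lam * u)^2))
    v <- u
    if (res <= tol) break
  }
  list(w = v, lambda = lam * scaleM)
}

# dual-space variant: power-iterate the Gram matrix K = Xi Xi^T of the
# already-deflated matrix and map the left vector back, w = Xi^T u /
# ||Xi^T u||.  Deflation has removed earlier components from Xi, so no
# extra orthogonalization is needed beyond rounding control.
.powerIterationDual <- function(Xi) {
  K <- tcrossprod(Xi)
  pit <- .powerIteration(K, matrix(0, nrow(K), 0L))
  if (is.null(pit) || pit$lambda <= 0) return(pit)
  w <- as.numeric(crossprod(Xi, pit$w))
  nw <- sqrt(sum(w^2))
  if (nw == 0) return(list(w = matrix(0, ncol(Xi), 1L), lambda = 0))
  list(w = matrix(w / nw, ncol = 1L), lambda = pit$lambda)
}

#' Fit a deflation-PCA basis
#'
#' Sequential principal-component extraction: the first component
#' maximizes the projected energy of the centered data matrix; each later
#' component maximizes the energy of the deflated matrix from which all
#' earlier components' contributions were subtracted.  Equivalent (up to
#' sign) to the dominant eigenvectors of \eqn{X^T X}.
#'
#' @param X numeric data matrix, n samples x d features, n >= 2.
#' @param k number of components, \code{k <= min(n, d)}.
#' @return A \linkS4class{PCABasis} with unit, pairwise-orthogonal
#'   components and non-increasing eigenvalues of the centered
#'   \eqn{X^T X}.
#' @export
pcaFit <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n < 2L) stop("need at least 2 samples")
  if (k < 1L || k > min(n, d))
    stop(sprintf("k = %d out of range; need 1 <= k <= min(n, d) = %d",
                 k, min(n, d)))
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  totalVar <- sum(Xc^2)
  W <- matrix(0, d, 0L)
  lambdas <- numeric(0L)
  zeroVar <- FALSE
  # with many more features than samples the deflated cross-product is
  # cheaper to iterate in the dual (Gram) space; same maximization,
  # identical components
  dual <- d > n
  for (i in seq_len(k)) {
    Xi <- Xc - Xc %*% W %*% t(W)
    pit <- if (dual) .powerIterationDual(Xi) else
      .powerIteration(crossprod(Xi), W)
    if (is.null(pit) || pit$lambda <= 1e-12 * max(totalVar, 1e-300) ||
        totalVar == 0) {
      # residual variance exhausted: complete with an arbitrary
      # orthonormal direction and a zero eigenvalue
      zeroVar <- TRUE
      cand <- diag(d)
      v <- NULL
      for (j in seq_len(d)) {
        u <- cand[, j]
        if (ncol(W) > 0L) u <- u - W %*% crossprod(W, u)
        if (sqrt(sum(u^2)) > 1e-6) { v <- u / sqrt(sum(u^2)); break }
      }
      W <- cbind(W, v)
      lambdas <- c(lambdas, 0)
    } else {
      w <- pit$w
      # deterministic sign: largest-magnitude loading positive
      w <- w * sign(w[which.max(abs(w))])
      W <- cbind(W, w)
      lambdas <- c(lambdas, pit$lambda)
    }
  }
  if (zeroVar)
    warning("data variance exhausted before k components; ",
            "remaining components are arbitrary orthonormal directions ",
            "with zero eigenvalue")
  dimnames(W) <- NULL
  new("PCABasis", components = W, eigenvalues = lambdas,
      center = as.numeric(center), nSamples = as.integer(n))
}

#' Project data onto a fitted basis
#'
#' @param X data matrix with the same feature dimension the basis was
#'   fitted on.
#' @param basis a \linkS4class{PCABasis}.
#' @param k number of leading components to keep (default: all).
#' @return n x k score matrix \code{(X - center) \%*\% W[, 1:k]}.
#' @export
pcaProject <- function(X, basis, k = ncol(pcaComponents(basis))) {
  X <- as.matrix(X)
  W <- pcaComponents(basis)
  if (ncol(X) != nrow(W)) stop("feature dimension mismatch")
  if (k < 1L || k > ncol(W))
    stop(sprintf("k = %d exceeds available components (%d)", k, ncol(W)))
  sweep(X, 2L, basis@center) %*% W[, seq_len(k), drop = FALSE]
}

#' Reconstruct data from component scores
#'
#' @param scores n x k score matrix from \code{\link{pcaProject}}.
#' @param basis the basis the scores came from.
#' @return n x d reconstruction \code{scores \%*\% t(W[, 1:k]) + center}.
#' @export
pcaReconstruct <- function(scores, basis) {
  scores <- as.matrix(scores)
  W <- pcaComponents(basis)
  k <- ncol(scores)
  if (k > ncol(W)) stop("more score columns than components")
  sweep(scores %*% t(W[, seq_len(k), drop = FALSE]), 2L, basis@center, `+`)
}

#' Component-score covariance matrix
#'
#' Returns the full matrix \eqn{Q[j,k] = (X w_j)^T (X w_k)}
#' \eqn{= \lambda_k w_j^T w_k} computed on centered data.  For a correctly
#' fitted orthogonal basis it is diagonal with the eigenvalues on the
#' diagonal; callers assert this to validate a fit.
#'
#' @param basis a \linkS4class{PCABasis} fitted on \code{X}.
#' @param X the data matrix the basis was fitted on.
#' @return k x k numeric matrix of score cross-products.
#' @export
pcaCovarianceCheck <- function(basis, X) {
  X <- as.matrix(X)
  W <- pcaComponents(basis)
  if (ncol(X) != nrow(W)) stop("feature dimension mismatch")
  S <- sweep(X, 2L, basis@center) %*% W
  crossprod(S)
}
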
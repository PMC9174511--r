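#' Graphical lasso precision-matrix estimate
#'
#' Maximizes the L1-penalized Gaussian log-likelihood
#' \deqn{\log\det K - \mathrm{tr}(SK) - \lambda \sum_{i \ne j} |K_{ij}|}
#' by the block-coordinate-descent algorithm: each column of the working
#' covariance is updated by solving a lasso regression via coordinate
#' descent, cycling until the working covariance stabilizes. At
#' \eqn{\lambda = 0} the solution is \eqn{S^{-1}} (computed directly when S
#' is positive definite).
#'
#' @param S p x p symmetric covariance/correlation matrix (a small ridge is
#'   added if S is not positive semidefinite).
#' @param lambda nonnegative scalar penalty on off-diagonal entries.
#' @param tol convergence tolerance on the mean absolute change of the
#'   working covariance, relative to the mean absolute off-diagonal of S.
#' @param max_iter maximum outer sweeps.
#' @param warm optional warm-start list with elements \code{W} and
#'   \code{Beta} from a previous solution on a nearby lambda.
#' @return list of class \code{"glasso_fit"}: \code{K} (precision),
#'   \code{W} (estimated covariance \eqn{K^{-1}}), \code{lambda},
#'   \code{iterations}, \code{converged}, \code{Beta} (for warm starts).
#' @export
glasso_solve <- function(S, lambda, tol = 1e-6, max_iter = 200, warm = NULL) {
  if (lambda < 0) stop_input("lambda must be nonnegative")
  p <- nrow(S)
  if (max(abs(S - t(S))) > 1e-8) stop_input("S must be symmetric")
  ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-8) S <- S + (1e-8 - ev_min) * diag(p)
  if (lambda == 0) {
    K <- solve(S)
    K <- (K + t(K)) / 2
    return(structure(list(K = K, W = S, lambda = 0, iterations = 0L,
                          converged = TRUE,
                          Beta = matrix(0, p, p)),
                     class = "glasso_fit"))
  }
  # penalty applies to off-diagonal entries only, so the stationary
  # diagonal of the working covariance equals that of S
  W <- warm$W %||% S
  diag(W) <- diag(S)
  Beta <- warm$Beta %||% matrix(0, p, p)
  s_off <- mean(abs(S[upper.tri(S)]))
  thr <- tol * max(s_off, 1e-12)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      V <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      beta <- Beta[idx, j]
      # lasso subproblem: min 1/2 b'Vb - s12'b + lambda |b|_1
      for (sweep in 1:100) {
        delta <- 0
        for (a in seq_along(idx)) {
          r <- s12[a] - sum(V[a, ] * beta) + V[a, a] * beta[a]
          new <- sign(r) * max(abs(r) - lambda, 0) / V[a, a]
          delta <- max(delta, abs(new - beta[a]))
          beta[a] <- new
        }
        if (delta < 1e-8) break
      }
      Beta[idx, j] <- beta
      w12 <- V %*% beta
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (mean(abs(W - W_old)) < thr) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("glasso did not converge in %d sweeps (lambda = %.4g, mean delta %.3g)",
                 max_iter, lambda, mean(abs(W - W_old))))
  }
  # recover K from the final W and regression coefficients
  K <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    beta <- Beta[idx, j]
    kjj <- 1 / (W[j, j] - sum(W[idx, j] * beta))
    K[j, j] <- kjj
    K[idx, j] <- -beta * kjj
  }
  K <- (K + t(K)) / 2
  # exact zeros where the lasso coefficient is zero
  K[abs(Beta) == 0 & abs(t(Beta)) == 0 & row(K) != col(K)] <- 0
  structure(list(K = K, W = W, lambda = lambda, iterations = it,
                 converged = converged, Beta = Beta),
            class = "glasso_fit")
}

#' Check the glasso stationarity (KKT) conditions
#'
#' At the solution, the gradient \eqn{W - S} must satisfy
#' \eqn{|W_{ij} - S_{ij}| \le \lambda} for zero off-diagonal entries of K
#' and \eqn{W_{ij} - S_{ij} = \lambda\,\mathrm{sign}(K_{ij})} for nonzero
#' ones (stationarity of the penalized log-likelihood, whose gradient is
#' \eqn{K^{-1} - S - \lambda\,\partial\|K\|_1}).
#'
#' @param fit \code{"glasso_fit"}.
#' @param S the input matrix.
#' @param tol numerical slack.
#' @return list with \code{max_violation} and \code{ok}.
#' @export
glasso_kkt <- function(fit, S, tol = 1e-4) {
  G <- fit$W - S
  off <- row(S) != col(S)
  zero <- off & fit$K == 0
  nz <- off & fit$K != 0
  v1 <- if (any(zero)) max(abs(G[zero])) - fit$lambda else -Inf
  v2 <- if (any(nz)) max(abs(G[nz] - fit$lambda * sign(fit$K[nz]))) else 0
  mv <- max(v1, v2)
  list(max_violation = mv, ok = mv <= tol)
}

#' Partial correlations from a precision matrix
#'
#' \eqn{\rho_{ij} = -K_{ij} / \sqrt{K_{ii} K_{jj}}}, diagonal set to 0.
#'
#' @param K symmetric positive-definite precision matrix.
#' @return partial-correlation matrix of the same dimension.
#' @export
precision_to_partial <- function(K) {
  if (max(abs(K - t(K))) > 1e-8) stop_input("K must be symmetric")
  if (min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop_input("K must be positive definite")
  }
  d <- sqrt(diag(K))
  P <- -K / tcrossprod(d)
  diag(P) <- 0
  dimnames(P) <- dimnames(K)
  P
}
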
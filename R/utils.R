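#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn %||%
#' @importFrom stats qnorm pnorm dnorm optimize optim cov var sd rnorm runif
#'   rbinom setNames complete.cases uniroot
#' @importFrom utils head
#' @importFrom broom tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' Re-exported generics
#'
#' \code{tidy} and \code{glance} from broom, \code{autoplot} from ggplot2,
#' so that itqnet result objects can be tidied and plotted without
#' attaching those packages.
#'
#' @name reexports
#' @aliases tidy glance autoplot
#' @export tidy
#' @export glance
#' @export autoplot
NULL

# Finite sentinel standing in for +/- infinity on the latent scale.
# pnorm(8.2) == 1 to double precision, so thresholds clamped here leave
# category probabilities untouched while keeping arithmetic finite.
.THRESH_CAP <- 8.2

stop_input <- function(msg, ...) abort(sprintf(msg, ...), class = "itqnet_input_error")

check_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_input("%s must lie in [0, 1]", what)
  }
  invisible(x)
}

check_scores <- function(x, what = "item scores") {
  bad <- !is.na(x) & (!(x %in% 0:4))
  if (any(bad)) {
    stop_input("%s must be integers in 0..4 (offending value: %s)",
               what, paste(head(unique(x[bad]), 3), collapse = ", "))
  }
  invisible(x)
}

is_corr_matrix <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    max(abs(m - t(m))) < tol &&
    max(abs(diag(m) - 1)) < tol
}

check_pd_corr <- function(m, name) {
  if (!is_corr_matrix(m)) {
    stop_input("%s must be a symmetric correlation matrix with unit diagonal", name)
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop_input("%s is not positive definite (smallest eigenvalue %.3g)", name, min(ev))
  }
  invisible(m)
}

# Gauss-Legendre nodes/weights on [-1, 1], precomputed once.
.gl <- local({
  n <- 48L
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1L, ]^2)
})

#' Standard bivariate normal CDF
#'
#' \eqn{P(X \le h, Y \le k)} for standard normal margins with correlation
#' \code{rho}, evaluated by Gauss-Legendre quadrature of the classical
#' single-integral identity
#' \deqn{\Phi_2(h,k,\rho) = \Phi(h)\Phi(k) + \frac{1}{2\pi}\int_0^{\rho}
#'   \frac{\exp\{-(h^2 - 2 t h k + k^2)/(2(1-t^2))\}}{\sqrt{1-t^2}}\,dt.}
#' Vectorized over \code{h} and \code{k} (recycled); \code{rho} is scalar.
#' Infinite bounds are clamped to a finite sentinel that is exact to double
#' precision. Used as the likelihood kernel of polychoric estimation.
#'
#' @param h,k upper integration bounds (numeric vectors).
#' @param rho scalar correlation in (-1, 1).
#' @return numeric vector of probabilities.
#' @export
pbvnorm <- function(h, k, rho) {
  if (length(rho) != 1L || !is.finite(rho) || abs(rho) >= 1) {
    stop_input("rho must be a scalar in (-1, 1)")
  }
  n <- max(length(h), length(k))
  h <- pmin(pmax(rep_len(h, n), -.THRESH_CAP), .THRESH_CAP)
  k <- pmin(pmax(rep_len(k, n), -.THRESH_CAP), .THRESH_CAP)
  base <- pnorm(h) * pnorm(k)
  if (rho == 0) return(base)
  # map nodes from [-1,1] to [0, rho]
  t <- rho / 2 * (.gl$nodes + 1)
  w <- rho / 2 * .gl$weights
  omt2 <- 1 - t * t
  # outer over (pair, node)
  hk <- h * k
  h2k2 <- h * h + k * k
  ex <- exp(-(outer(h2k2, rep(1, length(t))) - 2 * outer(hk, t)) /
              (2 * rep(omt2, each = n)))
  integ <- ex %*% (w / sqrt(omt2))
  pmin(pmax(base + as.vector(integ) / (2 * pi), 0), 1)
}
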
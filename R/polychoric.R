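#' Threshold estimates for an ordinal item
#'
#' First stage of two-step polychoric estimation: category-boundary
#' thresholds on the latent standard-normal scale, i.e. the normal quantiles
#' of the cumulative category proportions. Boundary proportions of 0 or 1
#' map to a large finite sentinel so that downstream bivariate-normal
#' rectangle probabilities stay well defined.
#'
#' @param counts nonnegative integer category counts (typically length 5 for
#'   0-4 Likert items).
#' @return numeric vector of \code{length(counts) - 1} nondecreasing
#'   thresholds.
#' @examples
#' estimate_thresholds(c(250, 250, 250, 183, 67))
#' @export
estimate_thresholds <- function(counts) {
  if (any(counts < 0) || sum(counts) < 1) stop_input("counts must be nonnegative with positive total")
  if (sum(counts > 0) < 2) {
    stop_input("degenerate item: all observations in a single category")
  }
  p <- cumsum(counts) / sum(counts)
  tau <- qnorm(p[-length(p)])
  pmin(pmax(tau, -.THRESH_CAP), .THRESH_CAP)
}

# Rectangle log-likelihood of an r x c table under a bivariate normal with
# the given thresholds and correlation rho.
.polychoric_loglik <- function(tab, tau_r, tau_c, rho) {
  a <- c(-.THRESH_CAP, tau_r, .THRESH_CAP)
  b <- c(-.THRESH_CAP, tau_c, .THRESH_CAP)
  F <- matrix(pbvnorm(rep(a, times = length(b)), rep(b, each = length(a)), rho),
              nrow = length(a))
  P <- F[-1, -1, drop = FALSE] - F[-nrow(F), -1, drop = FALSE] -
    F[-1, -ncol(F), drop = FALSE] + F[-nrow(F), -ncol(F), drop = FALSE]
  sum(tab * log(pmax(P, 1e-12)))
}

#' Polychoric correlation of a two-way ordinal contingency table
#'
#' Two-step maximum-likelihood estimate: thresholds are fixed at the normal
#' quantiles of the marginal cumulative proportions, then the latent
#' bivariate-normal correlation maximizes the rectangle-probability
#' likelihood over (-0.999, 0.999).
#'
#' @param tab matrix of nonnegative counts (rows = categories of item 1,
#'   columns = categories of item 2).
#' @return a list of class \code{"polychoric"} with elements \code{rho},
#'   \code{row_thresholds}, \code{col_thresholds}, \code{loglik}, \code{n}.
#' @examples
#' x <- cut(rnorm(500), c(-Inf, -1, 0, 1, Inf))
#' y <- cut(rnorm(500), c(-Inf, -1, 0, 1, Inf))
#' polychoric_pair(table(x, y))
#' @export
polychoric_pair <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || sum(tab) < 1) stop_input("table must hold nonnegative counts")
  if (sum(rowSums(tab) > 0) < 2 || sum(colSums(tab) > 0) < 2) {
    stop_input("degenerate table: need at least two nonempty rows and columns")
  }
  tau_r <- estimate_thresholds(rowSums(tab))
  tau_c <- estimate_thresholds(colSums(tab))
  opt <- optimize(function(r) .polychoric_loglik(tab, tau_r, tau_c, r),
                  interval = c(-0.999, 0.999), maximum = TRUE, tol = 1e-6)
  structure(
    list(rho = opt$maximum, row_thresholds = tau_r, col_thresholds = tau_c,
         loglik = opt$objective, n = sum(tab)),
    class = "polychoric"
  )
}

# Fast cross-tabulation of two integer vectors coded 0..4.
.cross_tab5 <- function(x, y) {
  matrix(tabulate(x * 5L + y + 1L, nbins = 25L), nrow = 5L, byrow = TRUE)
}

# Trim empty boundary categories (tabulate gives fixed 5x5).
.trim_tab <- function(tab) {
  tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
}

# Polychoric correlation vector (upper triangle, column-major order like
# R's upper.tri) for an n x p integer matrix coded 0..4.
.polychoric_vec <- function(items) {
  p <- ncol(items)
  idx <- which(upper.tri(diag(p)), arr.ind = TRUE)
  vapply(seq_len(nrow(idx)), function(k) {
    tab <- .trim_tab(.cross_tab5(items[, idx[k, 1]], items[, idx[k, 2]]))
    polychoric_pair(tab)$rho
  }, numeric(1))
}

#' Polychoric correlation matrix of an ordinal item matrix
#'
#' Pairwise two-step polychoric correlations over all item pairs, with an
#' eigenvalue-clipping repair to the nearest unit-diagonal positive
#' semidefinite matrix if the pairwise matrix is indefinite (flagged in the
#' result). Optionally estimates the weight matrix for weighted least
#' squares via \code{\link{wls_weight}}.
#'
#' @param items integer matrix or data frame, n subjects x p items, scores
#'   0-4, no missing values.
#' @param weights weight-matrix flavour: \code{"none"} (default; identity
#'   weighting downstream), \code{"diag"} or \code{"full"} (subject-level
#'   bootstrap; see \code{\link{wls_weight}}).
#' @param boot_B,boot_seed bootstrap resamples and seed when
#'   \code{weights != "none"}.
#' @return list of class \code{"polycor_matrix"}: \code{R} (p x p), per-item
#'   \code{thresholds}, \code{n}, \code{psd_repaired} flag, and \code{W}
#'   (NULL, or the q x q weight matrix, q = p(p-1)/2) plus weight metadata.
#' @export
polychoric_matrix <- function(items, weights = c("none", "diag", "full"),
                              boot_B = 200, boot_seed = 1L) {
  weights <- match.arg(weights)
  items <- as.matrix(items)
  labels <- colnames(items) %||% paste0("V", seq_len(ncol(items)))
  if (ncol(items) < 2) stop_input("need at least two items")
  if (anyNA(items)) stop_input("missing values are not allowed in polychoric_matrix")
  check_scores(items)
  storage.mode(items) <- "integer"
  p <- ncol(items)
  for (j in seq_len(p)) {
    if (length(unique(items[, j])) < 2) {
      stop_input("degenerate item '%s': fewer than two observed categories", labels[j])
    }
  }
  rho <- .polychoric_vec(items)
  R <- diag(p)
  R[upper.tri(R)] <- rho
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  repaired <- FALSE
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    repaired <- TRUE
    lam <- pmax(ev$values, 1e-6)
    R <- ev$vectors %*% diag(lam) %*% t(ev$vectors)
    d <- sqrt(diag(R))
    R <- R / tcrossprod(d)
    diag(R) <- 1
  }
  dimnames(R) <- list(labels, labels)
  thresholds <- lapply(seq_len(p), function(j) {
    estimate_thresholds(tabulate(items[, j] + 1L, nbins = 5L))
  })
  names(thresholds) <- labels
  out <- structure(
    list(R = R, thresholds = thresholds, n = nrow(items),
         psd_repaired = repaired, W = NULL, weight_type = weights,
         boot_B = NULL, boot_seed = NULL, ridge = NULL),
    class = "polycor_matrix"
  )
  if (weights != "none") {
    w <- wls_weight(items, B = boot_B, seed = boot_seed,
                    diagonal = identical(weights, "diag"))
    out$W <- w$W
    out$boot_B <- w$B
    out$boot_seed <- w$seed
    out$ridge <- w$ridge
  }
  out
}

#' Bootstrap weight matrix for WLS estimation on polychoric correlations
#'
#' Estimates the asymptotic covariance matrix of the vector of polychoric
#' correlations by a nonparametric bootstrap over subjects: the empirical
#' covariance of B resampled correlation vectors, rescaled by n so that
#' \code{W/n} approximates the sampling covariance at the observed sample
#' size (the convention under which the WLS discrepancy yields
#' \code{chi2 = (n-1) * F_min}). A small ridge proportional to the mean
#' diagonal is added for numerical positive definiteness and recorded.
#'
#' @param items n x p integer item matrix, scores 0-4.
#' @param B number of bootstrap resamples (at least 50; smaller values are
#'   refused as unstable).
#' @param seed integer seed for the resampling.
#' @param diagonal if TRUE return only the diagonal (as a diagonal matrix):
#'   the diagonally-weighted flavour recommended for n below ~500, where the
#'   full q x q matrix (q = 66 for the 12 ITQ items) is near singular.
#' @return list with \code{W} (q x q symmetric PD), \code{B}, \code{seed},
#'   \code{ridge}.
#' @export
wls_weight <- function(items, B = 200, seed = 1L, diagonal = FALSE) {
  if (B < 50) stop_input("B must be at least 50: smaller bootstraps give unstable weights")
  items <- as.matrix(items)
  storage.mode(items) <- "integer"
  n <- nrow(items)
  rhos <- withr_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      .polychoric_vec(items[idx, , drop = FALSE])
    }, numeric(ncol(items) * (ncol(items) - 1) / 2))
  })
  V <- n * cov(t(rhos))
  if (diagonal) {
    W <- diag(pmax(diag(V), 1e-10))
    ridge <- 0
  } else {
    ridge <- 1e-6 * mean(diag(V))
    W <- V + ridge * diag(nrow(V))
  }
  list(W = W, B = B, seed = as.integer(seed), ridge = ridge)
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
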
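#' Competing ITQ factor models
#'
#' The four structures commonly tested for the 12 ICD-11 symptom items:
#' \describe{
#'   \item{M1}{one common factor for all 12 items (12 free parameters,
#'     df 54).}
#'   \item{M2}{six correlated first-order factors, two items each
#'     (12 loadings + 15 factor correlations, df 39).}
#'   \item{M3}{six first-order factors plus a single second-order factor
#'     (12 + 6 parameters, df 48).}
#'   \item{M4}{six first-order factors plus correlated second-order PTSD
#'     and DSO factors (12 + 6 + 1 parameters, df 47).}
#' }
#' Identification: all factor variances fixed to 1; second-order
#' disturbances scaled so first-order factor variances stay 1 (the
#' higher-order loadings are correlations between first-order factors and
#' their second-order factor).
#'
#' @return named list of four \code{"factor_model_spec"} objects with
#'   fields \code{model_id}, \code{items}, \code{factor_index},
#'   \code{higher_order}, \code{q_free}, \code{df}.
#' @export
build_standard_models <- function() {
  items <- itq_symptom_items()
  base <- function(id, higher, q) {
    structure(list(model_id = id, items = items,
                   factor_index = rep(1:6, each = 2),
                   higher_order = higher, q_free = q, df = 66L - q),
              class = "factor_model_spec")
  }
  list(
    M1 = structure(list(model_id = "M1", items = items,
                        factor_index = rep(1L, 12),
                        higher_order = "none", q_free = 12L, df = 54L),
                   class = "factor_model_spec"),
    M2 = base("M2", "none", 27L),
    M3 = base("M3", "single", 18L),
    M4 = base("M4", "two_factor", 19L)
  )
}

# Unpack a parameter vector into loadings + factor correlation matrix.
.cfa_unpack <- function(theta, spec) {
  if (spec$model_id == "M1") {
    return(list(lambda = theta, phi = matrix(1, 1, 1), penalty = 0))
  }
  lambda <- theta[1:12]
  if (spec$higher_order == "none") {
    phi <- diag(6)
    phi[lower.tri(phi)] <- theta[13:27]
    phi[upper.tri(phi)] <- t(phi)[upper.tri(phi)]
    # keep Phi positive semidefinite during optimization by eigenvalue
    # bending; a penalty steers the optimizer back to the PSD region
    ev <- eigen(phi, symmetric = TRUE)
    pen <- 0
    if (min(ev$values) < 1e-4) {
      lam <- pmax(ev$values, 1e-4)
      pen <- sum((lam - ev$values)^2)
      phi <- ev$vectors %*% diag(lam) %*% t(ev$vectors)
      d <- sqrt(diag(phi))
      phi <- phi / tcrossprod(d)
    }
    return(list(lambda = lambda, phi = phi, penalty = pen))
  }
  if (spec$higher_order == "single") {
    g <- theta[13:18]
    phi <- tcrossprod(g)
    diag(phi) <- 1
    return(list(lambda = lambda, phi = phi, gamma = g, penalty = 0))
  }
  # two_factor: second-order PTSD (factors 1-3) and DSO (factors 4-6)
  g <- theta[13:18]
  rho <- theta[19]
  G <- matrix(0, 6, 2)
  G[1:3, 1] <- g[1:3]
  G[4:6, 2] <- g[4:6]
  psi <- matrix(c(1, rho, rho, 1), 2)
  phi <- G %*% psi %*% t(G)
  diag(phi) <- 1
  list(lambda = lambda, phi = phi, gamma = g, psi_rho = rho, penalty = 0)
}

#' Model-implied item correlation matrix
#'
#' \eqn{\Sigma(\theta) = \Lambda \Phi \Lambda^\top} off the diagonal, with
#' the diagonal fixed at 1 via unique variances \eqn{1 - \lambda_j^2}
#' (\eqn{\Phi} is structured from the second-order loadings for the
#' higher-order models).
#'
#' @param theta parameter vector in the model's native order (loadings,
#'   then factor correlations or second-order loadings).
#' @param spec a \code{"factor_model_spec"}.
#' @return 12x12 implied correlation matrix.
#' @export
implied_correlations <- function(theta, spec) {
  if (length(theta) != spec$q_free) {
    stop_input("theta must have length %d for model %s", spec$q_free, spec$model_id)
  }
  up <- .cfa_unpack(theta, spec)
  p <- length(spec$items)
  L <- matrix(0, p, max(spec$factor_index))
  L[cbind(seq_len(p), spec$factor_index)] <- up$lambda
  S <- L %*% up$phi %*% t(L)
  diag(S) <- 1
  S
}

.cfa_start <- function(spec) {
  switch(spec$model_id,
         M1 = rep(0.6, 12),
         M2 = c(rep(0.7, 12), rep(0.4, 15)),
         M3 = c(rep(0.7, 12), rep(0.6, 6)),
         M4 = c(rep(0.7, 12), rep(0.7, 6), 0.5))
}

.cfa_bounds <- function(spec) {
  q <- spec$q_free
  lower <- rep(-0.995, q)
  upper <- rep(0.995, q)
  # loadings kept positive for sign identification
  lower[1:12] <- 0.001
  if (spec$model_id %in% c("M3", "M4")) lower[13:18] <- 0.001
  list(lower = lower, upper = upper)
}

#' Fit a factor model by weighted least squares
#'
#' Minimizes the discrepancy
#' \eqn{F(\theta) = (s - \sigma(\theta))^\top W^{-1} (s - \sigma(\theta))}
#' over the 66 unique polychoric correlations, where W is the estimated
#' asymptotic covariance of s (\code{weights = "full"} or \code{"diag"}
#' from the estimate's bootstrap weight matrix) or the identity
#' (\code{"identity"}, unweighted least squares — the default when the
#' estimate carries no weight matrix). \code{chi2 = (n-1) * F_min} when a
#' proper weight matrix is used. Bounded quasi-Newton optimization with
#' multiple starts (one deterministic, the rest random under fixed seeds);
#' ties broken by lowest discrepancy.
#'
#' @param est \code{"polycor_matrix"} from \code{\link{polychoric_matrix}}
#'   (or a list with elements \code{R} and \code{n}).
#' @param spec \code{"factor_model_spec"}.
#' @param weights \code{"auto"} (use est$W if present, else identity),
#'   \code{"identity"}, \code{"diag"} or \code{"full"}.
#' @param n_starts number of optimizer starts (default 5).
#' @param seed seed for the random starts.
#' @return object of class \code{"cfa_fit"}: estimates, \code{F_min},
#'   \code{chi2}, \code{df}, \code{n}, \code{converged}, the sample and
#'   implied correlation vectors, and the weight spec.
#' @export
fit_wls <- function(est, spec, weights = "auto", n_starts = 5, seed = 1L) {
  R <- est$R
  n <- est$n
  p <- nrow(R)
  if (p != length(spec$items)) stop_input("correlation matrix has %d items, model needs %d", p, length(spec$items))
  s <- R[upper.tri(R)]
  q <- length(s)
  W <- NULL
  if (identical(weights, "auto")) {
    weights <- if (!is.null(est$W)) est$weight_type else "identity"
  }
  if (weights %in% c("full", "diag")) {
    if (is.null(est$W)) stop_input("estimate carries no weight matrix; rerun polychoric_matrix(weights=...)")
    W <- if (weights == "diag") diag(diag(est$W)) else est$W
  }
  Winv_half <- if (is.null(W)) diag(q) else {
    ch <- chol(W)
    backsolve(ch, diag(q), transpose = TRUE)
  }
  utri <- upper.tri(diag(p))
  objective <- function(theta) {
    Sg <- implied_correlations(theta, spec)
    r <- s - Sg[utri]
    v <- crossprod(Winv_half, r)
    sum(v * v) + 1e3 * .cfa_unpack(theta, spec)$penalty
  }
  bounds <- .cfa_bounds(spec)
  starts <- list(.cfa_start(spec))
  if (n_starts > 1) {
    starts <- c(starts, withr_seed(seed, {
      lapply(seq_len(n_starts - 1), function(i) {
        runif(spec$q_free, pmax(bounds$lower, 0.1), pmin(bounds$upper, 0.9))
      })
    }))
  }
  best <- NULL
  for (st in starts) {
    o <- tryCatch(
      optim(st, objective, method = "L-BFGS-B",
            lower = bounds$lower, upper = bounds$upper,
            control = list(maxit = 500, factr = 1e7)),
      error = function(e) NULL
    )
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop_input("optimization failed from all starts for model %s", spec$model_id)
  up <- .cfa_unpack(best$par, spec)
  F_min <- best$value
  structure(
    list(model_id = spec$model_id, spec = spec, theta = best$par,
         loadings = setNames(up$lambda, spec$items),
         factor_corr = up$phi, higher_loadings = up$gamma,
         higher_corr = up$psi_rho,
         F_min = F_min, chi2 = max((n - 1) * F_min, 0), df = spec$df,
         n = n, s = s, sigma_hat = implied_correlations(best$par, spec)[utri],
         weights = weights,
         converged = best$convergence == 0),
    class = "cfa_fit"
  )
}

#' Fit the saturated-null (independence) baseline model
#'
#' All correlations zero under the same weight matrix; reference point for
#' the incremental fit indices (CFI/TLI).
#'
#' @inheritParams fit_wls
#' @return minimal \code{"cfa_fit"}-like list with \code{chi2}, \code{df},
#'   \code{n}.
#' @export
fit_baseline <- function(est, weights = "auto") {
  R <- est$R
  n <- est$n
  q <- sum(upper.tri(R))
  s <- R[upper.tri(R)]
  W <- NULL
  if (identical(weights, "auto")) {
    weights <- if (!is.null(est$W)) est$weight_type else "identity"
  }
  if (weights %in% c("full", "diag")) {
    W <- if (weights == "diag") diag(diag(est$W)) else est$W
  }
  F_b <- if (is.null(W)) sum(s * s) else sum(s * solve(W, s))
  list(model_id = "baseline", chi2 = (n - 1) * F_b, df = q, n = n)
}

#' Fit indices for a WLS factor-model fit
#'
#' Standard normal-theory definitions:
#' RMSEA \eqn{= \sqrt{\max(\chi^2 - df, 0) / (df (n-1))}};
#' CFI \eqn{= 1 - \max(\chi^2-df,0)/\max(\chi^2_b-df_b, \chi^2-df, 0)};
#' TLI \eqn{= ((\chi^2_b/df_b) - (\chi^2/df)) / ((\chi^2_b/df_b) - 1)};
#' SRMR = root mean square of the 66 residual correlations; CD
#' \eqn{= 1 - \det(\hat\Theta)/\det(\hat\Sigma)} with \eqn{\hat\Theta} the
#' implied unique-variance diagonal; BIC \eqn{= -2 \ell_G + q_{free}\ln n}
#' with \eqn{\ell_G} the Gaussian pseudo-log-likelihood of the sample
#' correlation matrix under the implied one. Conventional cutoffs: CFI/TLI
#' at least 0.90 (adequate) / 0.95 (excellent); RMSEA at most 0.08 / 0.06.
#'
#' @param fit \code{"cfa_fit"}.
#' @param baseline baseline fit from \code{\link{fit_baseline}} (required
#'   for CFI/TLI; may be NULL, yielding NA for those indices).
#' @return tibble row: model_id, chi2, df, rmsea, cfi, tli, srmr, cd, bic.
#' @export
fit_indices <- function(fit, baseline = NULL) {
  chi2 <- fit$chi2
  df <- fit$df
  n <- fit$n
  rmsea <- rmsea_index(chi2, df, n)
  cfi <- tli <- NA_real_
  if (!is.null(baseline)) {
    cfi <- cfi_index(chi2, df, baseline$chi2, baseline$df)
    tli <- tli_index(chi2, df, baseline$chi2, baseline$df)
  }
  srmr <- sqrt(mean((fit$s - fit$sigma_hat)^2))
  p <- length(fit$spec$items)
  Sg <- implied_correlations(fit$theta, fit$spec)
  theta_diag <- 1 - diag(
    (function(l, fidx, phi) {
      L <- matrix(0, p, max(fidx))
      L[cbind(seq_len(p), fidx)] <- l
      L %*% phi %*% t(L)
    })(fit$loadings, fit$spec$factor_index, .cfa_unpack(fit$theta, fit$spec)$phi)
  )
  cd <- 1 - prod(pmax(theta_diag, 1e-12)) / det(Sg)
  R <- diag(p)
  R[upper.tri(R)] <- fit$s
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  ll <- gaussian_pseudo_loglik(R, Sg, n)
  bic <- -2 * ll + fit$spec$q_free * log(n)
  tibble::tibble(model_id = fit$model_id, chi2 = chi2, df = df,
                 rmsea = rmsea, cfi = cfi, tli = tli, srmr = srmr,
                 cd = cd, bic = bic)
}

#' Closed-form fit indices from test statistics
#'
#' The population-noncentrality indices as functions of the chi-square
#' statistic, its degrees of freedom and the sample size (and, for the
#' incremental indices, the independence-baseline statistic). These are
#' the formulas \code{\link{fit_indices}} applies to a fitted model; they
#' are exposed so published (chi-square, df, n) triples can be converted
#' directly.
#'
#' @param chi2,df model test statistic and degrees of freedom.
#' @param n sample size.
#' @param chi2_b,df_b baseline (independence-model) statistic and df.
#' @return numeric scalar.
#' @export
rmsea_index <- function(chi2, df, n) {
  if (df == 0) stop_input("df = 0: RMSEA undefined")
  sqrt(max(chi2 - df, 0) / (df * (n - 1)))
}

#' @rdname rmsea_index
#' @export
cfi_index <- function(chi2, df, chi2_b, df_b) {
  num <- max(chi2 - df, 0)
  den <- max(chi2_b - df_b, chi2 - df, 0)
  if (den > 0) 1 - num / den else 1
}

#' @rdname rmsea_index
#' @export
tli_index <- function(chi2, df, chi2_b, df_b) {
  rb <- chi2_b / df_b
  (rb - chi2 / df) / (rb - 1)
}

#' Gaussian pseudo-log-likelihood of a correlation matrix
#'
#' \eqn{\ell_G = -\frac{n-1}{2}\left[\log\det\hat\Sigma +
#' \mathrm{tr}(\hat\Sigma^{-1} R) - \log\det R - p\right]}; differences
#' between models are invariant to the additive constant.
#'
#' @param R sample correlation matrix.
#' @param Sigma implied correlation matrix.
#' @param n sample size.
#' @export
gaussian_pseudo_loglik <- function(R, Sigma, n) {
  p <- nrow(R)
  ldR <- determinant(R, logarithm = TRUE)$modulus[1]
  -(n - 1) / 2 *
    (determinant(Sigma, logarithm = TRUE)$modulus[1] +
       sum(diag(solve(Sigma, R))) - ldR - p)
}

#' Rank competing fits by BIC
#'
#' Ascending BIC; the lowest-BIC model is selected and marked decisive
#' when its BIC advantage over the runner-up exceeds 10 (the conventional
#' strong-evidence threshold).
#'
#' @param fits list of \code{"cfa_fit"} objects fitted to the same data.
#' @param baseline optional shared baseline fit for CFI/TLI.
#' @return list of class \code{"model_comparison"}: \code{table} (tibble of
#'   fit indices sorted by BIC), \code{selected}, \code{delta_bic},
#'   \code{decisive}.
#' @export
compare_models <- function(fits, baseline = NULL) {
  if (length(fits) < 2) stop_input("need at least two fits to compare")
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1) stop_input("fits must come from the same data (differing n)")
  tab <- dplyr::bind_rows(lapply(fits, fit_indices, baseline = baseline))
  tab <- dplyr::arrange(tab, .data$bic)
  delta <- tab$bic[2] - tab$bic[1]
  structure(
    list(table = tab, selected = tab$model_id[1], delta_bic = delta,
         decisive = delta > 10),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  print(x$table)
  cat(sprintf("Selected: %s (Delta-BIC to runner-up = %.2f%s)\n",
              x$selected, x$delta_bic,
              if (x$decisive) ", decisive" else ""))
  invisible(x)
}

#' @export
tidy.cfa_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = paste0("loading_", names(x$loadings)),
    estimate = unname(x$loadings)
  )
  if (x$model_id == "M2") {
    phi <- x$factor_corr
    idx <- which(lower.tri(phi), arr.ind = TRUE)
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = paste0("phi_", .FACTORS[idx[, 2]], "_", .FACTORS[idx[, 1]]),
      estimate = phi[idx]
    ))
  }
  if (!is.null(x$higher_loadings)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = paste0("gamma_", .FACTORS),
      estimate = x$higher_loadings
    ))
  }
  if (!is.null(x$higher_corr)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = "psi_PTSD_DSO", estimate = x$higher_corr
    ))
  }
  out
}

#' @export
glance.cfa_fit <- function(x, ...) {
  tibble::tibble(model_id = x$model_id, F_min = x$F_min, chi2 = x$chi2,
                 df = x$df, n = x$n, converged = x$converged)
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf("WLS CFA fit: model %s, chi2(%d) = %.2f, n = %d (%s weights)\n",
              x$model_id, x$df, x$chi2, x$n, x$weights))
  invisible(x)
}
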
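#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected Pearson statistic \eqn{\sum (O-E)^2/E} with expectations
#' from the margins (no continuity correction: the reconstructed
#' gender-by-exposure tables reproduce the reference statistics only
#' without it).
#'
#' @param tab 2x2 matrix of nonnegative counts, or the four counts
#'   \code{c(a, b, c, d)} filled column-wise.
#' @return tibble: \code{statistic}, \code{df}, \code{p_value}.
#' @export
pearson_chi2 <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(tab, 2)
  if (any(tab < 0)) stop_input("counts must be nonnegative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_input("zero margin: chi-square undefined")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value)
}

#' Prevalence with Wilson score interval
#'
#' Point estimate \eqn{100 k/n} percent and the 95\% Wilson score interval
#' (no continuity correction).
#'
#' @param k cases.
#' @param n denominator.
#' @param conf_level confidence level (default 0.95).
#' @return tibble: \code{k}, \code{n}, \code{point}, \code{ci_low},
#'   \code{ci_high} (all percentages).
#' @export
prevalence_ci <- function(k, n, conf_level = 0.95) {
  if (n <= 0) stop_input("denominator must be positive")
  if (k < 0 || k > n) stop_input("k must lie in [0, n]")
  ci <- suppressWarnings(
    stats::prop.test(k, n, conf.level = conf_level, correct = FALSE)$conf.int
  )
  tibble::tibble(k = k, n = n, point = 100 * k / n,
                 ci_low = 100 * ci[1], ci_high = 100 * ci[2])
}

#' Reconstruct a denominator from printed count/percent pairs
#'
#' A single pair gives \code{round(100 * count / percent)}. When several
#' printed rows share one denominator (e.g. PTSD and cPTSD rows of the
#' same gender column), all pairs can be passed at once: the denominator is
#' then chosen, among integers near the per-row estimates, to minimize the
#' summed squared mismatch between implied and printed percentages - this
#' resolves rows whose individual reconstruction falls on a rounding
#' boundary.
#'
#' @param count printed count(s).
#' @param percent printed percentage(s), same length.
#' @return list: \code{n} (integer denominator), \code{residual} (max
#'   absolute difference implied vs printed percent).
#' @export
reconstruct_denominator <- function(count, percent) {
  if (length(count) != length(percent)) stop_input("count and percent must have equal length")
  if (any(percent <= 0 & count > 0)) stop_input("zero percent with positive count")
  keep <- percent > 0
  if (!any(keep)) stop_input("need at least one positive percentage")
  est <- 100 * count[keep] / percent[keep]
  cand <- seq(max(1, floor(min(est)) - 2), ceiling(max(est)) + 2)
  sse <- vapply(cand, function(n) {
    sum((100 * count[keep] / n - percent[keep])^2)
  }, numeric(1))
  n <- cand[which.min(sse)]
  list(n = as.integer(n),
       residual = max(abs(100 * count[keep] / n - percent[keep])))
}

#' Multinomial logistic regression by Newton-Raphson
#'
#' Maximum-likelihood fit of a baseline-category logit model. The first
#' level of \code{y} is the reference (zero coefficients); each remaining
#' level gets its own coefficient vector. Newton iterations use the exact
#' block Hessian with step-halving, so the log-likelihood never decreases;
#' the Wald covariance is the inverse observed information. Diverging
#' coefficients (quasi-separation) are flagged, with estimates returned.
#'
#' @param y factor (or coercible) with at least two levels; for the
#'   diagnosis model, levels \code{none}, \code{PTSD}, \code{cPTSD}.
#' @param X numeric design matrix including an intercept column.
#' @param max_iter,tol Newton iteration controls.
#' @return object of class \code{"multinom_fit"}: \code{coef} (matrix,
#'   one row per non-reference level), \code{vcov}, \code{loglik},
#'   \code{converged}, \code{separation}, \code{levels}, \code{n},
#'   \code{loglik_trace}.
#' @export
fit_multinomial <- function(y, X, max_iter = 100, tol = 1e-10) {
  y <- droplevels(as.factor(y))
  K <- nlevels(y)
  if (K < 2) stop_input("y must have at least two observed categories")
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop_input("X and y sizes differ")
  if (qr(X)$rank < ncol(X)) stop_input("X is not of full column rank")
  n <- length(y)
  p <- ncol(X)
  m <- K - 1
  Y <- matrix(0, n, m)
  for (k in 2:K) Y[, k - 1] <- as.numeric(y == levels(y)[k])
  beta <- rep(0, m * p)
  loglik <- function(b) {
    B <- matrix(b, p, m)
    eta <- X %*% B
    denom <- log1p(rowSums(exp(eta)))
    sum(Y * eta) - sum(denom)
  }
  ll <- loglik(beta)
  trace <- ll
  converged <- FALSE
  H <- NULL
  for (it in seq_len(max_iter)) {
    B <- matrix(beta, p, m)
    eta <- X %*% B
    expeta <- exp(eta)
    P <- expeta / (1 + rowSums(expeta))
    grad <- as.vector(crossprod(X, Y - P))
    H <- matrix(0, m * p, m * p)
    for (a in seq_len(m)) {
      for (b in a:m) {
        Wab <- if (a == b) P[, a] * (1 - P[, a]) else -P[, a] * P[, b]
        blk <- crossprod(X, X * Wab)
        ra <- (a - 1) * p + seq_len(p)
        rb <- (b - 1) * p + seq_len(p)
        H[ra, rb] <- blk
        H[rb, ra] <- t(blk)
      }
    }
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    sz <- 1
    repeat {
      new_beta <- beta + sz * step
      new_ll <- loglik(new_beta)
      if (is.finite(new_ll) && new_ll >= ll - 1e-12) break
      sz <- sz / 2
      if (sz < 1e-8) break
    }
    beta <- beta + sz * step
    new_ll <- loglik(beta)
    trace <- c(trace, new_ll)
    if (abs(new_ll - ll) < tol * (abs(ll) + 1)) {
      ll <- new_ll
      converged <- TRUE
      break
    }
    ll <- new_ll
  }
  separation <- max(abs(beta)) > 15
  if (separation) {
    warn("possible separation: some coefficients diverge; estimates returned with caution")
  }
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, m * p, m * p))
  cf <- matrix(beta, p, m)
  cn <- colnames(X) %||% paste0("x", seq_len(p))
  coef <- t(cf)
  dimnames(coef) <- list(levels(y)[-1], cn)
  # parameters (and vcov) are blocked per non-reference level, p
  # coefficients each
  par_names <- as.vector(vapply(seq_len(m), function(k) {
    paste(levels(y)[k + 1], cn, sep = ":")
  }, character(p)))
  dimnames(vc) <- list(par_names, par_names)
  structure(
    list(coef = coef, vcov = vc, par_names = par_names,
         loglik = ll, loglik_trace = trace, converged = converged,
         separation = separation, levels = levels(y), n = n),
    class = "multinom_fit"
  )
}

#' @export
tidy.multinom_fit <- function(x, ...) {
  m <- nrow(x$coef)
  p <- ncol(x$coef)
  se <- sqrt(pmax(diag(x$vcov), 0))
  tibble::tibble(
    y_level = rep(rownames(x$coef), each = p),
    term = rep(colnames(x$coef), m),
    estimate = as.vector(t(x$coef)),
    std_error = se
  )
}

#' @export
glance.multinom_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, n = x$n, converged = x$converged,
                 separation = x$separation,
                 n_parameters = length(x$coef))
}

#' Odds ratios with Wald confidence intervals
#'
#' \eqn{OR = e^{\beta}}, CI \eqn{= e^{\beta \pm z_{1-\alpha/2}\,se}}.
#' Degenerate (zero-width) intervals from a zero standard error are
#' flagged.
#'
#' @param fit \code{"multinom_fit"}.
#' @param conf_level confidence level (default 0.95).
#' @return tibble: \code{y_level}, \code{term}, \code{or}, \code{ci_low},
#'   \code{ci_high}, \code{degenerate}.
#' @export
odds_ratios <- function(fit, conf_level = 0.95) {
  if (all(is.na(fit$vcov))) stop_input("fit carries no covariance matrix")
  td <- tidy.multinom_fit(fit)
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    y_level = td$y_level, term = td$term,
    or = exp(td$estimate),
    ci_low = exp(td$estimate - z * td$std_error),
    ci_high = exp(td$estimate + z * td$std_error),
    degenerate = td$std_error == 0
  )
}

#' Exposure-class design matrix for the diagnosis regression
#'
#' Builds the six exposure indicators (intentional/unintentional x
#' childhood/adolescence/6 months) and, if \code{adjusted}, gender,
#' non-Italian nationality and ordinal parental education, from a cohort
#' table.
#'
#' @param cohort cohort tibble with exposure flag columns and covariates.
#' @param adjusted include covariate adjustment columns.
#' @return numeric design matrix with intercept.
#' @export
exposure_design <- function(cohort, adjusted = FALSE) {
  cls <- classify_exposures(cohort)
  X <- cbind(
    `(Intercept)` = 1,
    int_child = as.numeric(cls$intentional_child),
    int_adol = as.numeric(cls$intentional_adol),
    int_6mo = as.numeric(cls$intentional_6mo),
    unint_child = as.numeric(cls$unintentional_child),
    unint_adol = as.numeric(cls$unintentional_adol),
    unint_6mo = as.numeric(cls$unintentional_6mo)
  )
  if (adjusted) {
    X <- cbind(
      X,
      female = as.numeric(cohort$gender == "female"),
      non_italian = as.numeric(cohort$nationality == "non-Italian"),
      parental_education = as.numeric(cohort$parental_education)
    )
  }
  X
}

#' Gender-contrast exposure and prevalence table
#'
#' Emits the classic validation-study table: for each checklist item and
#' for the aggregate exposure classes and diagnoses, the count and percent
#' per gender plus the uncorrected Pearson chi-square for the gender
#' contrast.
#'
#' @param cohort scored cohort tibble (must carry a \code{diagnosis}
#'   column, e.g. from \code{\link{itq_diagnose}}).
#' @param map event classification map.
#' @return tibble with one row per item/aggregate.
#' @export
gender_contrast_table <- function(cohort, map = event_classification_map()) {
  if (!"diagnosis" %in% names(cohort)) {
    stop_input("cohort must carry a diagnosis column; run itq_diagnose() first")
  }
  male <- cohort$gender == "male"
  cls <- classify_exposures(cohort, map)
  rows <- list()
  add_row <- function(label, class, ind, denom_ok = rep(TRUE, nrow(cohort))) {
    nm <- sum(ind & male & denom_ok, na.rm = TRUE)
    nf <- sum(ind & !male & denom_ok, na.rm = TRUE)
    dm <- sum(male & denom_ok, na.rm = TRUE)
    df_ <- sum(!male & denom_ok, na.rm = TRUE)
    stat <- tryCatch(
      pearson_chi2(matrix(c(nm, dm - nm, nf, df_ - nf), 2))$statistic,
      itqnet_input_error = function(e) NA_real_
    )
    tibble::tibble(row = label, class = class,
                   male_n = nm, male_pct = 100 * nm / dm,
                   female_n = nf, female_pct = 100 * nf / df_,
                   total_n = nm + nf, total_pct = 100 * (nm + nf) / (dm + df_),
                   chi2 = stat)
  }
  for (i in 1:21) {
    cols <- sprintf("item%02d_%s", i, .PERIODS)
    ind <- rowSums(as.matrix(cohort[cols]) * 1L) > 0
    cls_i <- map$class[map$item == i]
    rows[[length(rows) + 1]] <- add_row(as.character(i), cls_i %||% NA_character_, ind)
  }
  rows[[length(rows) + 1]] <- add_row("any_unintentional", NA, cls$unintentional_lifetime)
  rows[[length(rows) + 1]] <- add_row("any_intentional", NA, cls$intentional_lifetime)
  any_te <- rowSums(as.matrix(cohort[exposure_flag_columns()]) * 1L) > 0
  rows[[length(rows) + 1]] <- add_row("any_te", NA, any_te)
  ok <- !is.na(cohort$diagnosis)
  rows[[length(rows) + 1]] <- add_row("ptsd", NA, !is.na(cohort$diagnosis) & cohort$diagnosis == "PTSD", ok)
  rows[[length(rows) + 1]] <- add_row("cptsd", NA, !is.na(cohort$diagnosis) & cohort$diagnosis == "cPTSD", ok)
  dplyr::bind_rows(rows)
}
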
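test_that("threshold estimates are the normal quantiles of cumulative proportions", {
  tau <- estimate_thresholds(c(250, 250, 250, 183, 67))
  expect_equal(tau, qnorm(c(0.25, 0.50, 0.75, 0.933)), tolerance = 1e-8)
  expect_equal(tau[1:3], c(-0.6745, 0, 0.6745), tolerance = 1e-3)

  # uniform counts -> symmetric about zero
  tau_u <- estimate_thresholds(rep(200, 5))
  expect_equal(tau_u, -rev(tau_u), tolerance = 1e-12)

  # thresholds pushed back through the normal CDF reproduce the margins
  counts <- c(130, 210, 330, 220, 110)
  tau2 <- estimate_thresholds(counts)
  expect_equal(diff(c(0, pnorm(tau2), 1)), counts / sum(counts), tolerance = 1e-12)

  expect_error(estimate_thresholds(c(1000, 0, 0, 0, 0)), "degenerate")
})

test_that("bivariate normal CDF matches an independent implementation", {
  h <- c(-2.5, -1, 0, 0.7, 2, Inf, -0.3)
  k <- c(1.2, 0.4, -1.1, 2, -2, 0.5, Inf)
  for (rho in c(-0.9, -0.4, 0, 0.35, 0.8, 0.975)) {
    ref <- vapply(seq_along(h), function(i) {
      mvtnorm::pmvnorm(upper = c(min(h[i], 10), min(k[i], 10)),
                       corr = matrix(c(1, rho, rho, 1), 2))[1]
    }, numeric(1))
    expect_equal(pbvnorm(h, k, rho), ref, tolerance = 1e-10)
  }
})

test_that("polychoric pair recovers the generating correlation", {
  set.seed(42)
  n <- 20000
  z <- MASS::mvrnorm(n, c(0, 0), matrix(c(1, 0.5, 0.5, 1), 2))
  tau <- qnorm(c(0.2, 0.45, 0.7, 0.9))
  x <- findInterval(z[, 1], tau)
  y <- findInterval(z[, 2], tau)
  tab <- table(x, y)
  est <- polychoric_pair(tab)
  expect_s3_class(est, "polychoric")
  expect_equal(est$rho, 0.5, tolerance = 0.03)
  # transposition symmetry
  expect_equal(polychoric_pair(t(tab))$rho, est$rho, tolerance = 1e-6)
  # independent margins -> rho near zero
  ind <- outer(rowSums(tab), colSums(tab)) / n
  expect_equal(polychoric_pair(round(ind * 50))$rho, 0, tolerance = 0.02)
})

test_that("binary-table polychoric agrees with a brute-force likelihood grid", {
  tabs <- list(matrix(c(310, 120, 95, 475), 2),
               matrix(c(40, 60, 55, 45), 2),
               matrix(c(500, 20, 35, 445), 2))
  for (tab in tabs) {
    est <- polychoric_pair(tab)
    grid <- seq(-0.999, 0.999, by = 0.001)
    ll <- vapply(grid, function(r) {
      pr <- pbvnorm(est$row_thresholds, est$col_thresholds, r)
      p11 <- pr
      p1 <- pnorm(est$row_thresholds)   # P(X <= tau_row)
      p2 <- pnorm(est$col_thresholds)   # P(Y <= tau_col)
      P <- matrix(c(p11, p2 - p11, p1 - p11, 1 - p1 - p2 + p11), 2)
      sum(tab * log(pmax(P, 1e-12)))
    }, numeric(1))
    expect_lt(abs(est$rho - grid[which.max(ll)]), 0.002)
  }
})

test_that("polychoric matrix recovers the generating loading structure", {
  cond <- recovery_conditions()
  cfg <- default_sim_config(
    n_subjects = 20000, seed = 99,
    loadings = cond$loadings, factor_corr = cond$factor_corr,
    exposure_probs = array(0, c(21L, 3L, 2L))
  )
  coh <- generate_cohort(cfg)
  est <- polychoric_matrix(coh[, itq_symptom_items()])
  L <- matrix(0, 12, 6)
  L[cbind(1:12, rep(1:6, each = 2))] <- cond$loadings
  target <- L %*% cond$factor_corr %*% t(L)
  off <- upper.tri(target)
  expect_lt(max(abs(est$R[off] - target[off])), 0.03)
  expect_true(isSymmetric(est$R))
  expect_equal(diag(est$R), setNames(rep(1, 12), itq_symptom_items()))
  expect_gt(min(eigen(est$R, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("two-item matrix equals the pairwise estimate; duplicates are capped", {
  set.seed(7)
  x <- sample(0:4, 800, replace = TRUE, prob = c(0.4, 0.25, 0.15, 0.12, 0.08))
  y <- pmin(pmax(x + sample(-1:1, 800, replace = TRUE), 0), 4)
  m <- cbind(a = x, b = y)
  est <- polychoric_matrix(m)
  pair <- polychoric_pair(table(x, y))
  expect_equal(est$R["a", "b"], pair$rho, tolerance = 1e-6)

  dup <- cbind(a = x, b = x, c = y)
  est_dup <- polychoric_matrix(dup)
  expect_lt(est_dup$R["a", "b"], 1)
  expect_gt(est_dup$R["a", "b"], 0.99)
  expect_gt(min(eigen(est_dup$R, symmetric = TRUE, only.values = TRUE)$values), -1e-8)

  expect_error(polychoric_matrix(cbind(a = rep(2L, 50), b = x[1:50])), "degenerate")
})

test_that("bootstrap weight matrix is deterministic, refuses tiny B, scales as 1/n", {
  set.seed(31)
  z <- MASS::mvrnorm(500, rep(0, 4), diag(4) * 0.5 + 0.5)
  tau <- qnorm(c(0.3, 0.6, 0.8, 0.95))
  m <- apply(z, 2, findInterval, vec = tau)
  expect_error(wls_weight(m, B = 20), "at least 50")
  w1 <- wls_weight(m, B = 60, seed = 5)
  w2 <- wls_weight(m, B = 60, seed = 5)
  expect_identical(w1$W, w2$W)

  # variance of each correlation shrinks ~1/n (W is n * cov, so the raw
  # bootstrap variance W/n should fall with slope about -1 in log-log)
  ns <- c(500, 2000, 8000)
  v <- vapply(ns, function(n) {
    set.seed(n)
    z <- MASS::mvrnorm(n, rep(0, 4), diag(4) * 0.5 + 0.5)
    m <- apply(z, 2, findInterval, vec = tau)
    mean(diag(wls_weight(m, B = 200, seed = 1)$W)) / n
  }, numeric(1))
  slope <- coef(lm(log(v) ~ log(ns)))[2]
  expect_lt(abs(slope + 1), 0.25)
})

test_that("independent item blocks give near-zero cross-block weight covariance", {
  set.seed(77)
  n <- 2000
  r <- matrix(c(1, 0.6, 0.6, 1), 2)
  z <- cbind(MASS::mvrnorm(n, c(0, 0), r), MASS::mvrnorm(n, c(0, 0), r))
  tau <- qnorm(c(0.25, 0.5, 0.75, 0.92))
  m <- apply(z, 2, findInterval, vec = tau)
  W <- wls_weight(m, B = 200, seed = 3)$W
  # correlation order for p=4: (1,2), (1,3), (2,3), (1,4), (2,4), (3,4);
  # within-block pairs are (1,2) and (3,4)
  cross_cov <- abs(W[1, 6])
  within_var <- sqrt(W[1, 1] * W[6, 6])
  expect_lt(cross_cov / within_var, 0.15)
})
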
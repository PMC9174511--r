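test_that("Pearson chi-square is uncorrected and symmetric in rows/columns", {
  tab <- matrix(c(28, 469, 63, 423), 2)
  res <- pearson_chi2(tab)
  expect_equal(res$df, 1)
  expect_equal(res$statistic, 15.7126, tolerance = 1e-3)
  expect_equal(pearson_chi2(tab[2:1, ])$statistic, res$statistic)
  expect_equal(pearson_chi2(tab[, 2:1])$statistic, res$statistic)
  expect_equal(pearson_chi2(matrix(c(20, 80, 40, 160), 2))$statistic, 0)
  expect_error(pearson_chi2(matrix(c(0, 0, 5, 10), 2)), "margin")
})

test_that("chi-square null rejection rate is calibrated at the 5% level", {
  set.seed(101)
  reps <- 10000
  n_per_group <- 500
  a <- rbinom(reps, n_per_group, 0.3)
  b <- rbinom(reps, n_per_group, 0.3)
  # closed-form Pearson statistic for the simulated tables...
  p_pool <- (a + b) / (2 * n_per_group)
  stat <- (a - b)^2 / (2 * n_per_group * p_pool * (1 - p_pool))
  # ...verified against the implementation on a subsample
  for (i in seq(1, reps, by = 997)) {
    tab <- matrix(c(a[i], n_per_group - a[i], b[i], n_per_group - b[i]), 2)
    expect_equal(pearson_chi2(tab)$statistic, stat[i], tolerance = 1e-10)
  }
  rate <- mean(stat > qchisq(0.95, 1))
  expect_gte(rate, 0.042)
  expect_lte(rate, 0.058)
})

test_that("prevalence point estimates and Wilson intervals behave", {
  p1 <- prevalence_ci(91, 999)
  expect_equal(round(p1$point, 2), 9.11)
  expect_true(p1$ci_low < p1$point && p1$point < p1$ci_high)

  p0 <- prevalence_ci(0, 100)
  expect_equal(p0$point, 0)
  expect_equal(p0$ci_low, 0)

  p50 <- prevalence_ci(50, 100)
  expect_equal(p50$point, 50)
  expect_equal(p50$ci_high - 50, 50 - p50$ci_low, tolerance = 1e-10)

  expect_error(prevalence_ci(5, 0), "positive")
  expect_error(prevalence_ci(11, 10), "\\[0, n\\]")
})

test_that("denominators are reconstructed from printed count/percent pairs", {
  expect_equal(reconstruct_denominator(28, 5.63)$n, 497L)
  expect_equal(reconstruct_denominator(63, 12.96)$n, 486L)
  expect_equal(reconstruct_denominator(50, 50.0)$n, 100L)
  # rows sharing a denominator resolve rounding-boundary cases jointly
  joint <- reconstruct_denominator(c(28, 10), c(5.63, 2.01))
  expect_equal(joint$n, 497L)
  expect_lt(joint$residual, 0.02)
  expect_error(reconstruct_denominator(5, 0), "zero percent")
})

test_that("multinomial Newton fit matches the established optimizer", {
  set.seed(15)
  n <- 2000
  X <- cbind(1, x1 = rbinom(n, 1, 0.4), x2 = rnorm(n))
  y <- draw_multinomial(X, c(-1.5, 0.8, 0.4), c(-2.5, 1.2, -0.3))
  fit <- fit_multinomial(y, X)
  expect_true(fit$converged)
  expect_false(fit$separation)
  # log-likelihood is nondecreasing across iterations (step-halving)
  expect_true(all(diff(fit$loglik_trace) >= -1e-9))

  ref <- nnet::multinom(y ~ X[, -1], trace = FALSE, reltol = 1e-13, maxit = 500)
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-4)
  se <- matrix(sqrt(diag(fit$vcov)), ncol = ncol(X), byrow = TRUE)
  expect_equal(unname(se), unname(summary(ref)$standard.errors), tolerance = 1e-3)
  expect_gte(fit$loglik, -ref$value - 1e-6)
})

test_that("binary collapse reduces to the 2x2 cross-product odds ratio", {
  set.seed(16)
  n <- 4000
  x <- rbinom(n, 1, 0.4)
  y2 <- rbinom(n, 1, plogis(-1.2 + 0.9 * x))
  y <- factor(ifelse(y2 == 1, "case", "none"), levels = c("none", "case"))
  fit <- fit_multinomial(y, cbind(1, x = x))
  a <- sum(x == 1 & y == "case"); b <- sum(x == 1 & y == "none")
  cc <- sum(x == 0 & y == "case"); d <- sum(x == 0 & y == "none")
  expect_equal(exp(fit$coef["case", "x"]), (a * d) / (b * cc), tolerance = 1e-6)
})

test_that("null predictors give odds ratios near one with covering intervals", {
  set.seed(17)
  n <- 10000
  X <- cbind(1, exposure = rbinom(n, 1, 0.5), noise = rbinom(n, 1, 0.3))
  y <- draw_multinomial(X, c(-2, 0.7, 0), c(-3, 0.9, 0))
  ors <- odds_ratios(fit_multinomial(y, X))
  null_rows <- ors[ors$term == "noise", ]
  expect_true(all(null_rows$ci_low < 1 & 1 < null_rows$ci_high))
  expect_true(all(abs(log(null_rows$or)) < 0.35))
})

test_that("odds-ratio intervals follow the Wald closed form", {
  fit <- list(coef = matrix(c(0, log(2)), 1,
                            dimnames = list("PTSD", c("a", "b"))),
              vcov = diag(c(0.1^2, 0)), levels = c("none", "PTSD"), n = 10)
  class(fit) <- "multinom_fit"
  ors <- odds_ratios(fit)
  expect_equal(ors$or, c(1, 2))
  expect_equal(ors$ci_low[1], exp(-1.96 * 0.1), tolerance = 1e-4)
  expect_equal(ors$ci_high[1], exp(1.96 * 0.1), tolerance = 1e-4)
  expect_equal(round(ors$ci_low[1], 2), 0.82)
  expect_equal(round(ors$ci_high[1], 2), 1.22)
  expect_true(ors$degenerate[2])
})

test_that("the gender contrast table reproduces its inputs on a known cohort", {
  coh <- itq_diagnose(generate_cohort(default_sim_config(n_subjects = 800, seed = 5)))
  tab <- gender_contrast_table(coh)
  expect_equal(nrow(tab), 26)  # 21 items + 3 aggregates + 2 diagnoses
  r15 <- tab[tab$row == "15", ]
  cols <- sprintf("item15_%s", c("child", "adol", "6mo"))
  ind <- rowSums(as.matrix(coh[cols])) > 0
  expect_equal(r15$total_n, sum(ind))
  expect_equal(r15$male_n, sum(ind & coh$gender == "male"))
  # chi-square equals a direct computation on the same 2x2
  nm <- sum(coh$gender == "male")
  tab22 <- matrix(c(r15$male_n, nm - r15$male_n,
                    r15$female_n, nrow(coh) - nm - r15$female_n), 2)
  expect_equal(r15$chi2, pearson_chi2(tab22)$statistic)
})
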
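test_that("generation is deterministic given the seed", {
  cfg <- default_sim_config(n_subjects = 300, seed = 123)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  c3 <- generate_cohort(default_sim_config(n_subjects = 300, seed = 124))
  expect_false(identical(c1, c3))
})

test_that("null-exposure cohorts have no flags and threshold-implied marginals", {
  cfg <- default_sim_config(
    n_subjects = 20000, seed = 21,
    exposure_probs = array(0, c(21L, 3L, 2L)),
    exposure_effects = matrix(0, 8, 6)
  )
  coh <- generate_cohort(cfg)
  expect_true(all(!as.matrix(coh[exposure_flag_columns()])))
  expect_true(all(!coh$trauma_exposed))

  # category frequencies vs normal-orthant probabilities: each cell within
  # 3 MC SEs, allowing the single borderline excursion that 20 simultaneous
  # 3-sigma checks produce by chance (none may pass 4 SEs)
  z_all <- unlist(lapply(c("Re1", "Dys1", "Nsc2", "Pimp1"), function(it) {
    tau <- cfg$thresholds[[it]]
    expected <- diff(c(0, pnorm(tau), 1))
    observed <- tabulate(coh[[it]] + 1L, nbins = 5) / nrow(coh)
    (observed - expected) / sqrt(expected * (1 - expected) / nrow(coh))
  }))
  expect_lte(sum(abs(z_all) > 3), 1)
  expect_true(all(abs(z_all) <= 4))
})

test_that("ordinal sampling follows the graded-response measurement model", {
  set.seed(5)
  n <- 10000
  latent <- matrix(rnorm(2 * n), n, 2)

  # loading zero -> item carries no factor signal
  m0 <- sample_ordinal_items(latent, loadings = 0, latent_index = 1,
                             thresholds = list(qnorm(c(0.3, 0.5, 0.7, 0.9))))
  expect_lt(abs(cor(m0[, 1], latent[, 1])), 0.03)

  # fixed thresholds -> normal orthant category proportions
  tau <- c(-0.6745, 0, 0.6745, 1.5)
  m1 <- sample_ordinal_items(latent, loadings = 0.5, latent_index = 2,
                             thresholds = list(tau))
  props <- tabulate(m1[, 1] + 1L, nbins = 5) / n
  expect_equal(props, c(0.25, 0.25, 0.25, 0.1832, 0.0668), tolerance = 0.02)

  # two items with loading 0.8 on one factor -> polychoric near 0.64
  set.seed(6)
  z <- matrix(rnorm(20000), ncol = 1)
  m2 <- sample_ordinal_items(z, loadings = c(0.8, 0.8), latent_index = c(1, 1),
                             thresholds = list(tau, tau))
  est <- polychoric_pair(table(m2[, 1], m2[, 2]))
  expect_equal(est$rho, 0.64, tolerance = 0.03)

  expect_error(
    sample_ordinal_items(latent, loadings = 1.2, latent_index = 1,
                         thresholds = list(tau)),
    "loadings"
  )
  expect_error(
    sample_ordinal_items(latent, loadings = 0.5, latent_index = 1,
                         thresholds = list(c(0, 0, 1, 2))),
    "strictly increasing"
  )
})

test_that("exposure draws honour gender-specific probabilities", {
  probs <- array(0, c(21L, 3L, 2L))
  set.seed(3)
  g <- rep(c("male", "female"), 100)
  expect_true(all(!as.matrix(generate_exposures(200, g, probs))))

  probs[4, 2, ] <- 1
  flags <- generate_exposures(200, g, probs)
  expect_true(all(flags$item04_adol))
  expect_error(generate_exposures(100, g, probs), "length")

  # default probabilities reproduce the reference lifetime intentional rates
  set.seed(14)
  g2 <- rep(c("male", "female"), each = 1000)
  fl <- generate_exposures(2000, g2, default_exposure_probs())
  cls <- classify_exposures(fl)
  male_int <- mean(cls$intentional_lifetime[g2 == "male"])
  female_int <- mean(cls$intentional_lifetime[g2 == "female"])
  expect_lt(abs(100 * male_int - 53.69), 3)
  expect_lt(abs(100 * female_int - 67.47), 3)
})

test_that("config validation rejects malformed structures", {
  bad_fc <- matrix(0.99, 6, 6)
  diag(bad_fc) <- 1
  bad_fc[1, 2] <- bad_fc[2, 1] <- -0.99
  expect_error(default_sim_config(n_subjects = 10, factor_corr = bad_fc),
               "factor_corr")
  expect_error(default_sim_config(n_subjects = 10, loadings = rep(1.5, 12)),
               "loadings")
  expect_error(default_sim_config(n_subjects = 10, female_share = 1.3),
               "female_share")
})

test_that("latent exposure shifts raise diagnosis rates among the exposed", {
  eff <- matrix(0, 8, 6)
  eff[, 1] <- 1  # +1 SD on every factor for intentional-childhood exposure
  probs <- array(0, c(21L, 3L, 2L))
  probs[4, 1, ] <- 0.5
  cfg <- default_sim_config(n_subjects = 5000, seed = 8,
                            exposure_probs = probs, exposure_effects = eff)
  coh <- itq_diagnose(generate_cohort(cfg), require_exposure = FALSE)
  exposed <- coh$item04_child
  rate <- function(ind) mean(coh$diagnosis[ind] == "cPTSD")
  expect_gt(rate(exposed), rate(!exposed))

  # direction confirmed by a larger Monte-Carlo run of the same process
  cfg_big <- default_sim_config(n_subjects = 100000, seed = 9,
                                exposure_probs = probs, exposure_effects = eff)
  big <- itq_diagnose(generate_cohort(cfg_big), require_exposure = FALSE)
  expect_gt(mean(big$diagnosis[big$item04_child] == "cPTSD"),
            mean(big$diagnosis[!big$item04_child] == "cPTSD"))
})

test_that("cohorts round-trip through CSV", {
  cfg <- default_sim_config(n_subjects = 50, seed = 4)
  coh <- generate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, path, config = cfg)
  back <- read_cohort_table(path)
  plain <- setdiff(names(coh), "parental_education")
  expect_equal(as.data.frame(back[plain]), as.data.frame(coh[plain]),
               ignore_attr = TRUE)
  expect_equal(as.character(back$parental_education),
               as.character(coh$parental_education))
  expect_true(file.exists(paste0(path, ".config.json")))
  meta <- jsonlite::read_json(paste0(path, ".config.json"))
  expect_equal(meta$seed, 4L)
})
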
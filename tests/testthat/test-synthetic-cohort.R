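# Synthetic cohort generator: determinism, marginal and correlation
# structure, and the closed-form moments of the zero-inflated NB sampler.

test_that("covariate generation is a pure function of (spec, seed)", {
  specs <- list(covariate_spec("a", "continuous", mean = 1, sd = 2),
                covariate_spec("b", "binary", prevalence = 0.4),
                covariate_spec("c", "categorical", levels = c("x", "y"),
                               probs = c(0.7, 0.3)))
  t1 <- generate_covariates(100, specs, seed = 7)
  t2 <- generate_covariates(100, specs, seed = 7)
  expect_identical(t1, t2)
  expect_equal(dim(t1), c(100L, 4L))  # id + 3 covariates
  t3 <- generate_covariates(100, specs, seed = 8)
  expect_false(identical(t1, t3))
})

test_that("latent blocks induce the declared correlation and marginals", {
  specs <- list(
    covariate_spec("x1", "continuous", block_id = 1, block_rho = 0.8),
    covariate_spec("x2", "continuous", block_id = 1, block_rho = 0.8),
    covariate_spec("b1", "binary", prevalence = 0.3))
  tab <- generate_covariates(10000, specs, seed = 42)
  expect_gt(cor(tab$x1, tab$x2), 0.75)
  expect_lt(cor(tab$x1, tab$x2), 0.85)
  expect_gt(mean(tab$b1), 0.27)   # 3 * binomial SE at n = 1e4 is ~0.014
  expect_lt(mean(tab$b1), 0.33)
})

test_that("categorical level frequencies match their probabilities", {
  specs <- list(covariate_spec("c", "categorical",
                               levels = c("a", "b", "c"),
                               probs = c(0.5, 0.3, 0.2)))
  tab <- generate_covariates(10000, specs, seed = 5)
  freq <- table(tab$c) / 10000
  for (l in names(freq)) {
    p <- c(a = 0.5, b = 0.3, c = 0.2)[[l]]
    expect_lt(abs(freq[[l]] - p), 3 * sqrt(p * (1 - p) / 10000))
  }
})

test_that("invalid specs are rejected", {
  expect_error(covariate_spec("x", "categorical", levels = c("a", "b"),
                              probs = c(0.5, 0.4)), "sum to 1")
  expect_error(covariate_spec("x", "continuous", sd = 0), "sd > 0")
  expect_error(covariate_spec("x", "binary", prevalence = 1.2), "prevalence")
  expect_error(covariate_spec("x", "continuous", block_rho = 1), "block_rho")
  specs <- list(covariate_spec("a", "continuous"),
                covariate_spec("a", "binary", prevalence = 0.5))
  expect_error(generate_covariates(10, specs, 1), "duplicate")
})

test_that("outcome sampler hits its closed-form limits", {
  specs <- list(covariate_spec("x", "continuous"))
  cov10k <- generate_covariates(10000, specs, seed = 1)

  # pi ~ 1: every outcome is a structural zero
  all0 <- generate_outcome(cov10k[1:200, , drop = FALSE],
                           ground_truth(gamma0 = 50, beta0 = 2, theta = 1),
                           seed = 2)
  expect_true(all(all0$wmh_volume_mm3 == 0))

  # pi ~ 0 and theta -> Inf: Poisson limit, mean = exp(beta0) = 5
  pois <- generate_outcome(cov10k,
                           ground_truth(gamma0 = -50, beta0 = log(5),
                                        theta = 1e6), seed = 3)
  expect_gt(mean(pois$wmh_volume_mm3), 4.8)
  expect_lt(mean(pois$wmh_volume_mm3), 5.2)
})

test_that("zero fraction matches pi + (1 - pi) (theta/(theta+mu))^theta", {
  n <- 20000
  specs <- list(covariate_spec("x", "continuous"))
  cov <- generate_covariates(n, specs, seed = 4)
  pi <- 0.3; mu <- 2; theta <- 1
  out <- generate_outcome(cov, ground_truth(gamma0 = qlogis(pi),
                                            beta0 = log(mu), theta = theta),
                          seed = 5)
  p0 <- pi + (1 - pi) * (theta / (theta + mu))^theta
  se <- sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(mean(out$wmh_volume_mm3 == 0) - p0), 3 * se)
  # and the mean matches (1 - pi) * mu
  m <- (1 - pi) * mu
  se_m <- sd(out$wmh_volume_mm3) / sqrt(n)
  expect_lt(abs(mean(out$wmh_volume_mm3) - m), 3 * se_m)
})

test_that("with pi = 0 the variance matches mu + mu^2 / theta", {
  n <- 20000
  specs <- list(covariate_spec("x", "continuous"))
  cov <- generate_covariates(n, specs, seed = 6)
  mu <- 5; theta <- 2
  out <- generate_outcome(cov, ground_truth(gamma0 = -50, beta0 = log(mu),
                                            theta = theta), seed = 7)
  y <- out$wmh_volume_mm3
  v_expect <- mu + mu^2 / theta
  # SE of the sample variance from the empirical fourth moment
  m4 <- mean((y - mean(y))^4)
  se_v <- sqrt((m4 - var(y)^2) / n)
  expect_lt(abs(var(y) - v_expect), 3 * se_v)
})

test_that("truth referencing an unknown variable errors", {
  specs <- list(covariate_spec("x", "continuous"))
  cov <- generate_covariates(50, specs, seed = 1)
  expect_error(generate_outcome(cov, ground_truth(beta = c(nope = 1)), 1),
               "unknown variable")
})

test_that("the KORA-like fixture carries the published exclusion structure", {
  fx <- make_kora_like_fixture(seed = 1)
  expect_identical(nrow(fx), 400L)
  expect_identical(sum(fx$flag_insufficient_quality), 12L)
  expect_identical(sum(fx$flag_other_aetiology), 2L)
  expect_identical(sum(fx$flag_missing_covariates), 16L)
  # flag sets are disjoint
  expect_identical(sum(fx$flag_insufficient_quality |
                       fx$flag_other_aetiology |
                       fx$flag_missing_covariates), 30L)
  expect_identical(make_kora_like_fixture(seed = 1), fx)
  # unflagged rows are fully populated
  keep <- !(fx$flag_insufficient_quality | fx$flag_other_aetiology |
            fx$flag_missing_covariates)
  expect_false(anyNA(fx[keep, ]))
})

test_that("ready-made scenarios have the declared panel sizes", {
  k <- scenario_kora_like()
  s <- scenario_ship_like()
  expect_identical(length(k$specs), 90L)
  expect_identical(length(s$specs), 34L)
  expect_identical(k$n, 400L)
  expect_identical(s$n, 854L)
  expect_identical(sum(k$truth$beta != 0), 10L)
  expect_true(all(abs(k$truth$beta) >= 0.1 & abs(k$truth$beta) <= 0.5))
  # replication scenario shares the discovery effects present in its panel
  expect_true(all(names(s$truth$beta) %in% names(k$truth$beta)))
  expect_equal(s$truth$beta, k$truth$beta[names(s$truth$beta)])
})
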
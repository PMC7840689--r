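# Likelihoods, the EM fitter, prediction and model-comparison metrics.

test_that("nb_log_pmf matches independent evaluations of the gamma formula", {
  expect_equal(nb_log_pmf(0, 1, 1), log(0.5), tolerance = 1e-12)
  # independent oracle 1: term-by-term gamma-function formula
  direct <- function(y, mu, theta)
    log(gamma(y + theta) / (gamma(theta) * factorial(y)) *
          (theta / (theta + mu))^theta * (mu / (theta + mu))^y)
  expect_equal(nb_log_pmf(3, 2, 5), direct(3, 2, 5), tolerance = 1e-10)
  # independent oracle 2: stats::dnbinom over a grid
  for (y in c(0L, 1L, 7L, 40L))
    for (mu in c(0.5, 2, 20))
      expect_equal(nb_log_pmf(y, mu, 1.7),
                   dnbinom(y, size = 1.7, mu = mu, log = TRUE),
                   tolerance = 1e-10)
})

test_that("nb_log_pmf normalizes and reaches the Poisson limit", {
  s <- sum(exp(nb_log_pmf(0:500, rep(2, 501), 1)))
  expect_gte(s, 1 - 1e-8)
  expect_lte(s, 1 + 1e-12)
  # the exact NB(theta) vs Poisson gap is ~ (y - mu)^2 / (2 theta), so at
  # theta = 1e8 counts up to 50 agree to ~1.3e-5 and shrink as 1/theta
  for (mu in c(0.5, 3, 10)) {
    y <- 0:50
    gap <- max(abs(nb_log_pmf(y, rep(mu, 51), 1e8) - dpois(y, mu, log = TRUE)))
    expect_lt(gap, (max(y) - mu)^2 / (2 * 1e8) + 1e-6)
    expect_lt(max(abs(nb_log_pmf(y, rep(mu, 51), 1e10) -
                        dpois(y, mu, log = TRUE))), 1e-5)
  }
  expect_error(nb_log_pmf(-1, 1, 1), "non-negative")
  expect_error(nb_log_pmf(1, 0, 1), "mu")
  expect_error(nb_log_pmf(1, 1, -2), "theta")
})

test_that("zinb_loglik equals a direct per-row mixture computation", {
  set.seed(31)
  X <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("a", "b")))
  y <- c(0, 3, 0, 7, 1, 0)
  pr <- zinb_params(beta0 = 1.2, beta = c(0.5, -0.3), gamma0 = -0.4,
                    gamma = c(0.2, 0.1), theta = 1.3)
  # brute force, written independently of the package internals
  mu <- exp(1.2 + X %*% c(0.5, -0.3))
  pi <- 1 / (1 + exp(-(-0.4 + X %*% c(0.2, 0.1))))
  ll <- 0
  for (i in 1:6) {
    f <- dnbinom(y[i], size = 1.3, mu = mu[i])
    ll <- ll + if (y[i] == 0) log(pi[i] + (1 - pi[i]) * f)
               else log((1 - pi[i]) * f)
  }
  expect_equal(zinb_loglik(pr, list(X = X, y = y)), ll, tolerance = 1e-8)
})

test_that("zinb_loglik reduces to NB when pi ~ 0 and to 0 for certain zeros", {
  set.seed(32)
  X <- matrix(rnorm(30), 15, 2)
  y <- rpois(15, 4)
  pr <- zinb_params(beta0 = 1, beta = c(0.2, -0.1), gamma0 = -50,
                    gamma = c(0, 0), theta = 2)
  mu <- exp(1 + drop(X %*% c(0.2, -0.1)))
  expect_equal(zinb_loglik(pr, list(X = X, y = y)),
               sum(nb_log_pmf(y, mu, 2)), tolerance = 1e-8)
  pr2 <- zinb_params(beta0 = 1, beta = c(0, 0), gamma0 = 50,
                     gamma = c(0, 0), theta = 2)
  expect_equal(zinb_loglik(pr2, list(X = X, y = rep(0, 15))), 0,
               tolerance = 1e-6)
  expect_error(zinb_loglik(pr, list(X = X[, 1, drop = FALSE], y = y)),
               "width")
})

test_that("at lambda >= lambda_max the fit collapses onto the null model", {
  s <- sim_design(200, 5, seed = 21, beta = c(0.6, -0.4, 0, 0, 0))
  lm_ <- compute_lambda_max(s$design, alpha = 0.8)
  fit <- fit_zinb_en(s$design, 0.8, lm_, "zinb")
  expect_length(fit$active_set, 0)
  null <- fit_null(s$design$y, "zinb")
  expect_equal(fit$loglik, null$loglik, tolerance = 1e-6)
  # below lambda_max the signal enters
  fit2 <- fit_zinb_en(s$design, 0.8, lm_ / 2, "zinb")
  expect_gt(length(fit2$active_set), 0)
  # coefficients are exact zeros, not small values
  expect_true(all(fit$params$beta == 0))
  expect_true(all(fit$params$gamma == 0))
})

test_that("unpenalized ZINB nests NB on data with zeros", {
  s <- sim_design(300, 2, seed = 22, beta = c(0.5, 0), pi = 0.3)
  fz <- fit_zinb_en(s$design, 1, 0, "zinb")
  fn <- fit_zinb_en(s$design, 1, 0, "nb")
  expect_gte(fz$loglik, fn$loglik - 1e-6)
})

test_that("null models predict the sample mean and respect nesting", {
  set.seed(23)
  y <- rnbinom(120, size = 1, mu = 2798)
  for (fam in c("zinb", "nb")) {
    nf <- fit_null(y, fam)
    pred <- predict_expected_volume(nf, list(X = matrix(0, 120, 0), y = y))
    expect_equal(pred[1], mean(y), tolerance = 1e-6 * mean(y))
    expect_true(all(pred == pred[1]))
  }
  # zero-free outcome: pi-hat ~ 0 and mu-hat ~ mean
  y2 <- y + 1
  nf2 <- fit_null(y2, "zinb")
  expect_lt(plogis(nf2$params$gamma0), 1e-4)
  expect_equal(exp(nf2$params$beta0), mean(y2), tolerance = 0.01 * mean(y2))
  expect_error(fit_null(rep(0, 50), "nb"), "all zero")
})

test_that("unpenalized NB fit agrees with the independent glm.nb route", {
  skip_if_not_installed("MASS")
  s <- sim_design(500, 3, seed = 24, beta = c(0.5, -0.3, 0), pi = 0)
  fit <- fit_zinb_en(s$design, 1, 0, "nb")
  df <- data.frame(y = s$design$y, s$design$X)
  ref <- MASS::glm.nb(y ~ v1 + v2 + v3, data = df)
  expect_equal(unname(fit$params$beta), unname(coef(ref)[-1]),
               tolerance = 1e-3)
  expect_equal(fit$params$beta0, unname(coef(ref)[1]), tolerance = 1e-3)
  expect_equal(fit$params$theta, ref$theta, tolerance = 0.01 * ref$theta)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-4)
})

test_that("expected-volume predictions obey the mixture identities", {
  set.seed(25)
  X <- matrix(rnorm(40), 20, 2)
  pr0 <- zinb_params(beta0 = 2, beta = c(0.3, 0), gamma0 = -50,
                     gamma = c(0, 0), theta = 1)
  mu <- exp(2 + drop(X %*% c(0.3, 0)))
  expect_equal(predict_expected_volume(pr0, list(X = X)), mu,
               tolerance = 1e-8)
  pr1 <- zinb_params(beta0 = 2, beta = c(0.3, 0), gamma0 = 50,
                     gamma = c(0, 0), theta = 1)
  expect_lt(max(predict_expected_volume(pr1, list(X = X))), 1e-12 * max(mu))
  expect_true(all(predict_expected_volume(pr0, list(X = X)) >= 0))
})

test_that("predictions match the Monte-Carlo mean of the generator", {
  specs <- list(covariate_spec("x", "continuous"))
  cov <- generate_covariates(20000, specs, seed = 26)
  cov$x <- 1  # fixed covariate value
  truth <- ground_truth(beta = c(x = 0), gamma = c(x = 0),
                        beta0 = log(8), gamma0 = qlogis(0.4), theta = 2)
  out <- generate_outcome(cov, truth, seed = 27)
  pr <- zinb_params(beta0 = log(8), beta = numeric(0), gamma0 = qlogis(0.4),
                    gamma = numeric(0), theta = 2)
  pred <- predict_expected_volume(pr, list(X = matrix(0, 1, 0)))
  se <- sd(out$wmh_volume_mm3) / sqrt(20000)
  expect_lt(abs(mean(out$wmh_volume_mm3) - pred), 3 * se)
})

test_that("rmse identities", {
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(c(0, 2), c(0, 0)), sqrt(2))
  set.seed(28)
  y <- rnbinom(200, size = 1, mu = 50)
  expect_equal(rmse(rep(mean(y), 200), y), sqrt(mean((y - mean(y))^2)))
  expect_error(rmse(numeric(0), numeric(0)), "non-empty")
})

test_that("likelihood-ratio test follows its definition", {
  mk <- function(ll, k) structure(list(loglik = ll, k = k),
                                  class = "zinb_fit")
  same <- likelihood_ratio_test(mk(-100, 4), mk(-100, 4))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  lrt <- likelihood_ratio_test(mk(-95, 7), mk(-100, 4))
  expect_equal(lrt$statistic, 10)
  expect_equal(lrt$df, 3)
  expect_equal(lrt$p, pchisq(10, 3, lower.tail = FALSE))
  expect_error(likelihood_ratio_test(mk(-101, 7), mk(-100, 4)), "nested")
})

test_that("unpenalized fits recover simulation truth (scaled-down)", {
  s <- sim_design(1500, 6, seed = 29, beta = c(0.5, -0.5, 0, 0, 0, 0),
                  beta0 = 4, theta = 2, pi = 0.25)
  fit <- fit_zinb_en(s$design, 1, 1e-6, "zinb")
  expect_true(fit$converged)
  expect_lt(max(abs(fit$params$beta - s$beta)), 0.12)
  expect_lt(abs(fit$params$theta - 2) / 2, 0.3)
  expect_lt(abs(plogis(fit$params$gamma0) - 0.25), 0.06)
})

test_that("fit serialization round-trips the coefficient names", {
  s <- sim_design(100, 3, seed = 30, beta = c(0.5, 0, 0))
  fit <- fit_zinb_en(s$design, 0.8, 0.05, "zinb")
  js <- jsonlite::fromJSON(fit_to_json(fit))
  expect_equal(sort(names(js$beta)), sort(colnames(s$design$X)))
  expect_equal(js$loglik, fit$loglik, tolerance = 1e-12)
  expect_equal(js$aic, fit$aic, tolerance = 1e-12)
})
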
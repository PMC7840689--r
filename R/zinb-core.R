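# Penalized zero-inflated negative binomial regression: likelihoods, the
# EM / coordinate-descent fitter, lambda_max and the lambda path, prediction
# and model-comparison metrics.

ETA_CAP <- 30  # cap on linear predictors; exp(30) ~ 1e13 >> any mm^3 volume

#' Negative binomial log-pmf (NB2 parameterization)
#'
#' `log P(Y = y)` for the NB2 distribution with mean `mu` and dispersion
#' `theta` (variance `mu + mu^2 / theta`), computed in log-space:
#' `lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
#'  theta * (log theta - log(theta + mu)) + y * (log mu - log(theta + mu))`.
#'
#' @param y non-negative integer count(s).
#' @param mu mean(s), `> 0`.
#' @param theta dispersion, `> 0`.
#' @return numeric vector of log-probabilities.
#' @export
nb_log_pmf <- function(y, mu, theta) {
  if (any(!is.finite(y)) || any(y < 0) || any(y != floor(y)))
    abort_validation("y must be non-negative integer")
  if (any(!is.finite(mu)) || any(mu <= 0))
    abort_validation("mu must be positive")
  if (any(!is.finite(theta)) || any(theta <= 0))
    abort_validation("theta must be positive")
  # lgamma(y + theta) - lgamma(theta) cancels catastrophically for huge
  # theta; for small counts the ratio is the exact product log sum
  ratio <- if (max(theta) > 1e6 && max(y) <= 1000) {
    if (length(theta) == 1) theta <- rep(theta, length(y))
    vapply(seq_along(y), function(i)
      sum(log(theta[i] + seq_len(y[i]) - 1)), numeric(1))
  } else {
    lgamma(y + theta) - lgamma(theta)
  }
  ratio - lgamma(y + 1) -
    theta * log1p(mu / theta) +
    y * (log(mu) - log(theta + mu))
}

#' Construct a ZINB parameter object
#'
#' @param beta0,gamma0 count-part and zero-part intercepts.
#' @param beta,gamma coefficient vectors over the design columns (log
#'   incidence-rate and log-odds scales); `gamma` is ignored for
#'   `family = "nb"`.
#' @param theta NB dispersion, `> 0`.
#' @param family `"zinb"` or `"nb"`.
#' @return an object of class `zinb_params`.
#' @export
zinb_params <- function(beta0 = 0, beta = numeric(), gamma0 = 0,
                        gamma = numeric(), theta = 1,
                        family = c("zinb", "nb")) {
  family <- match.arg(family)
  if (!is.finite(theta) || theta <= 0) abort_validation("theta must be > 0")
  if (family == "zinb" && length(gamma) != length(beta))
    abort_validation("beta and gamma must have equal length")
  if (!all(is.finite(c(beta0, beta, gamma0, gamma))))
    abort_validation("all coefficients must be finite")
  structure(list(beta0 = beta0, beta = beta, gamma0 = gamma0,
                 gamma = gamma, theta = theta, family = family),
            class = "zinb_params")
}

.linpreds <- function(params, X) {
  n <- nrow(X)
  eta_mu <- rep(params$beta0, n) + if (ncol(X)) drop(X %*% params$beta) else 0
  eta_mu <- pmin(pmax(eta_mu, -ETA_CAP), ETA_CAP)
  if (params$family == "zinb") {
    eta_pi <- rep(params$gamma0, n) +
      if (ncol(X)) drop(X %*% params$gamma) else 0
    eta_pi <- pmin(pmax(eta_pi, -ETA_CAP), ETA_CAP)
  } else eta_pi <- rep(-Inf, n)
  list(eta_mu = eta_mu, eta_pi = eta_pi, mu = exp(eta_mu))
}

.as_design <- function(X, y = NULL) {
  if (inherits(X, "zinb_design")) return(X)
  if (is.list(X) && !is.null(X$X)) return(X)
  list(X = X, y = y)
}

#' Zero-inflated negative binomial log-likelihood
#'
#' For rows with `y = 0` the zero mixture
#' `log(pi + (1 - pi) * NB(0; mu, theta))` is evaluated with log-sum-exp;
#' positive rows contribute `log(1 - pi) + nb_log_pmf(y, mu, theta)`. With
#' `family = "nb"` (or `pi ~ 0`) this reduces to the plain NB log-likelihood.
#'
#' @param params a [zinb_params()] object.
#' @param design a `zinb_design` (or list with elements `X`, `y`).
#' @return the scalar log-likelihood.
#' @export
zinb_loglik <- function(params, design) {
  d <- .as_design(design)
  X <- d$X; y <- d$y
  if (length(params$beta) != ncol(X))
    abort_validation("coefficient length does not match design width")
  lp <- .linpreds(params, X)
  lnb <- nb_log_pmf(y, lp$mu, params$theta)
  if (params$family == "nb") return(sum(lnb))
  log_pi <- plogis(lp$eta_pi, log.p = TRUE)
  log_1mpi <- plogis(-lp$eta_pi, log.p = TRUE)
  zero <- y == 0
  sum(log_add_exp(log_pi[zero], log_1mpi[zero] + lnb[zero])) +
    sum(log_1mpi[!zero] + lnb[!zero])
}

.penalty <- function(params, alpha, lambda) {
  b <- c(params$beta, if (params$family == "zinb") params$gamma)
  lambda * sum(alpha * abs(b) + (1 - alpha) / 2 * b^2)
}

# Penalized objective: mean negative log-likelihood + elastic-net penalty.
# The mean (not sum) keeps lambda_max stable in n.
.zinb_objective <- function(params, design, alpha, lambda) {
  -zinb_loglik(params, design) / length(design$y) +
    .penalty(params, alpha, lambda)
}

#' Fitting controls for the EM / coordinate-descent algorithm
#'
#' @param max_em_iters maximum EM iterations.
#' @param em_tol relative tolerance on the penalized objective.
#' @param max_irls_iters IRLS iterations per M-step component.
#' @param cd_max_sweeps maximum coordinate-descent sweeps per IRLS step.
#' @param cd_tol coefficient-change tolerance for coordinate descent.
#' @param theta_range search bracket for the dispersion.
#' @return a list of controls.
#' @export
zinb_controls <- function(max_em_iters = 200, em_tol = 1e-6,
                          max_irls_iters = 5, cd_max_sweeps = 1000,
                          cd_tol = 1e-8, theta_range = c(1e-3, 1e6)) {
  list(max_em_iters = max_em_iters, em_tol = em_tol,
       max_irls_iters = max_irls_iters, cd_max_sweeps = cd_max_sweeps,
       cd_tol = cd_tol, theta_range = theta_range)
}

# E-step: posterior structural-zero weights (0 for positive counts).
.estep <- function(params, X, y) {
  if (params$family == "nb") return(rep(0, length(y)))
  lp <- .linpreds(params, X)
  z <- numeric(length(y))
  zero <- y == 0
  if (any(zero)) {
    log_pi <- plogis(lp$eta_pi[zero], log.p = TRUE)
    log_1mpi <- plogis(-lp$eta_pi[zero], log.p = TRUE)
    lp0 <- nb_log_pmf(0, lp$mu[zero], params$theta)
    z[zero] <- exp(log_pi - log_add_exp(log_pi, log_1mpi + lp0))
  }
  z
}

# One penalized IRLS block (logistic or NB with fixed theta), via the C++
# coordinate-descent kernel. Returns updated (b0, b).
.irls_enet <- function(X, y, kind, u, theta, b0, b, alpha, lambda, controls) {
  for (it in seq_len(controls$max_irls_iters)) {
    eta <- rep(b0, nrow(X)) + if (ncol(X)) drop(X %*% b) else 0
    eta <- pmin(pmax(eta, -ETA_CAP), ETA_CAP)
    if (kind == "logistic") {
      p <- plogis(eta)
      w <- pmax(p * (1 - p), 1e-5)
      r <- eta + (y - p) / w
    } else {  # NB count part, working response on the log scale
      mu <- exp(eta)
      w <- pmax(u * mu * theta / (theta + mu), 1e-10)
      r <- eta + (y - mu) / mu
    }
    sol <- .cd_wls_enet(X, w, r, alpha, lambda, b0, b,
                        controls$cd_max_sweeps, controls$cd_tol)
    delta <- max(abs(sol$b0 - b0), if (ncol(X)) max(abs(sol$beta - b)) else 0)
    b0 <- sol$b0; b <- sol$beta
    if (delta < 1e-7) break
  }
  list(b0 = b0, b = b)
}

.update_theta <- function(y, mu, u, theta_range) {
  f <- function(lt) -sum(u * nb_log_pmf(y, mu, exp(lt)))
  opt <- optimize(f, log(theta_range), tol = 1e-4)
  exp(opt$minimum)
}

.interp_params <- function(a, b, t) {
  # convex combination on (beta, gamma, intercepts, log theta)
  zinb_params(beta0 = (1 - t) * a$beta0 + t * b$beta0,
              beta = (1 - t) * a$beta + t * b$beta,
              gamma0 = (1 - t) * a$gamma0 + t * b$gamma0,
              gamma = if (a$family == "zinb")
                (1 - t) * a$gamma + t * b$gamma else a$gamma,
              theta = exp((1 - t) * log(a$theta) + t * log(b$theta)),
              family = a$family)
}

.df_count <- function(params) {
  if (params$family == "zinb")
    2L + sum(params$beta != 0) + sum(params$gamma != 0) + 1L
  else
    1L + sum(params$beta != 0) + 1L
}

.make_fit <- function(params, design, alpha, lambda, trace, iters, converged) {
  ll <- zinb_loglik(params, design)
  k <- .df_count(params)
  cn <- colnames(design$X)
  names(params$beta) <- cn
  if (params$family == "zinb") names(params$gamma) <- cn
  structure(list(
    params = params, loglik = ll,
    penalized_objective = trace[length(trace)],
    objective_trace = trace, aic = 2 * k - 2 * ll, k = k,
    active_set = cn[params$beta != 0],
    active_set_zero = if (params$family == "zinb") cn[params$gamma != 0]
                      else character(),
    n_em_iters = iters, converged = converged,
    alpha = alpha, lambda = lambda, family = params$family,
    n = length(design$y)), class = "zinb_fit")
}

# Crude intercept-only starting values.
.init_params <- function(y, family, theta = 1) {
  pos_mean <- if (any(y > 0)) mean(y[y > 0]) else 0.5
  zf <- min(max(mean(y == 0), 0.02), 0.98)
  zinb_params(beta0 = log(max(pos_mean, 0.1)),
              beta = numeric(0), gamma0 = qlogis(zf),
              gamma = numeric(0), theta = theta, family = family)
}

.expand_params <- function(p0, pcols, family) {
  zinb_params(beta0 = p0$beta0, beta = numeric(pcols),
              gamma0 = p0$gamma0, gamma = if (family == "zinb")
                numeric(pcols) else numeric(0),
              theta = p0$theta, family = family)
}

#' Fit an elastic-net-penalized (zero-inflated) negative binomial model
#'
#' Minimises the penalized objective
#' `-(1/n) loglik + lambda * sum_j [alpha |b_j| + (1 - alpha)/2 b_j^2]`,
#' where the penalty covers both count-part (`beta`) and zero-part (`gamma`)
#' coefficients; intercepts and the dispersion `theta` are unpenalized. The
#' algorithm is EM (posterior structural-zero weights in the E-step) with
#' penalized IRLS + coordinate-descent M-steps for each part and a Brent
#' search on `log theta`. Soft-thresholding leaves inactive coefficients at
#' exactly zero, and a step-halving safeguard keeps the penalized objective
#' non-increasing across EM iterations.
#'
#' @param design a standardized `zinb_design`.
#' @param alpha elastic-net mixing in `(0, 1]` (1 = lasso).
#' @param lambda penalty strength, `>= 0`.
#' @param family `"zinb"` or `"nb"`.
#' @param controls see [zinb_controls()].
#' @param init optional warm-start [zinb_params()].
#' @return an object of class `zinb_fit`.
#' @export
fit_zinb_en <- function(design, alpha, lambda, family = c("zinb", "nb"),
                        controls = zinb_controls(), init = NULL) {
  family <- match.arg(family)
  d <- .as_design(design)
  X <- d$X; y <- d$y
  n <- length(y)
  if (n < 10) abort_validation("need at least 10 observations")
  if (all(y == 0)) abort_validation("outcome vector is all zero")
  if (alpha <= 0 || alpha > 1) abort_validation("alpha must be in (0, 1]")
  if (lambda < 0) abort_validation("lambda must be >= 0")
  p <- ncol(X)

  # default initialization: the converged intercept-only fit, so that the
  # null model is an exact EM fixed point whenever lambda >= lambda_max
  # (intercept-only fits themselves start from moment-based values)
  if (is.null(init)) {
    init <- if (p == 0) {
      .expand_params(.init_params(y, family), 0L, family)
    } else {
      # tight tolerance: a loosely converged starting point can strand a
      # coefficient just inside the active set at lambda ~ lambda_max
      tight <- controls
      tight$em_tol <- min(controls$em_tol, 1e-12)
      tight$max_em_iters <- max(controls$max_em_iters, 500)
      .expand_params(fit_null(y, family, tight)$params, p, family)
    }
  }
  params <- init
  if (length(params$beta) != p)
    abort_validation("init does not match design width")

  obj <- .zinb_objective(params, d, alpha, lambda)
  trace <- obj
  converged <- FALSE
  iters <- 0L
  for (iter in seq_len(controls$max_em_iters)) {
    iters <- iter
    prev <- params
    z <- .estep(params, X, y)
    u <- 1 - z
    cand <- params
    if (family == "zinb") {
      gfit <- .irls_enet(X, z, "logistic", u = NULL, theta = NULL,
                         cand$gamma0, cand$gamma, alpha, lambda, controls)
      cand$gamma0 <- gfit$b0; cand$gamma <- gfit$b
    }
    if (sum(u) > 1e-8) {
      bfit <- .irls_enet(X, y, "nb", u = u, theta = cand$theta,
                         cand$beta0, cand$beta, alpha, lambda, controls)
      cand$beta0 <- bfit$b0; cand$beta <- bfit$b
      mu <- exp(pmin(pmax(rep(cand$beta0, n) +
        (if (p) drop(X %*% cand$beta) else 0), -ETA_CAP), ETA_CAP))
      cand$theta <- .update_theta(y, mu, u, controls$theta_range)
    }
    new_obj <- .zinb_objective(cand, d, alpha, lambda)
    # safeguard: the M-step's IRLS approximation can overshoot; halve back
    halvings <- 0
    while (new_obj > obj + 1e-12 && halvings < 12) {
      cand <- .interp_params(prev, cand, 0.5)
      new_obj <- .zinb_objective(cand, d, alpha, lambda)
      halvings <- halvings + 1
    }
    if (new_obj > obj + 1e-12) {  # no descent available: stop at prev
      params <- prev
      converged <- TRUE
      break
    }
    params <- cand
    trace <- c(trace, new_obj)
    if (abs(obj - new_obj) < controls$em_tol * (abs(obj) + 1e-10)) {
      obj <- new_obj
      converged <- TRUE
      break
    }
    obj <- new_obj
  }
  .make_fit(params, d, alpha, lambda, trace, iters, converged)
}

#' Fit the intercept-only null model
#'
#' The null model carries no covariates and predicts the same expected
#' volume — the sample mean — for every participant (for the ZINB null this
#' holds exactly at the MLE: `(1 - pi) * mu = mean(y)`).
#'
#' @param y outcome vector of non-negative integers.
#' @param family `"zinb"` or `"nb"`.
#' @param controls see [zinb_controls()].
#' @return a `zinb_fit`.
#' @export
fit_null <- function(y, family = c("zinb", "nb"), controls = zinb_controls()) {
  family <- match.arg(family)
  d <- list(X = matrix(numeric(0), nrow = length(y), ncol = 0), y = y)
  fit_zinb_en(d, alpha = 1, lambda = 0, family = family, controls = controls)
}

#' Expected outcome under a fitted model
#'
#' `E[Y | x] = (1 - pi(x)) * mu(x)`; for a plain NB model `pi = 0`.
#'
#' @param params a [zinb_params()] (or a `zinb_fit`, whose parameters are
#'   used).
#' @param design design matrix / `zinb_design` to predict for.
#' @return non-negative numeric vector of expected volumes.
#' @export
predict_expected_volume <- function(params, design) {
  if (inherits(params, "zinb_fit")) params <- params$params
  d <- .as_design(design)
  if (length(params$beta) != ncol(d$X))
    abort_validation("coefficient length does not match design width")
  lp <- .linpreds(params, d$X)
  pi <- if (params$family == "zinb") plogis(lp$eta_pi) else 0
  (1 - pi) * lp$mu
}

#' Root mean squared error
#' @param pred,obs equal-length numeric vectors.
#' @return `sqrt(mean((pred - obs)^2))`.
#' @export
rmse <- function(pred, obs) {
  if (!length(pred) || length(pred) != length(obs))
    abort_validation("pred and obs must be non-empty and equal length")
  sqrt(mean((pred - obs)^2))
}

#' Likelihood-ratio test of a full model against a nested null
#'
#' @param full,null `zinb_fit` objects on the same data, `null` nested in
#'   `full`. Degrees of freedom are the difference in the lasso-df counts
#'   (nonzero coefficients + intercepts + theta).
#' @return list with `statistic`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, null) {
  stat <- 2 * (full$loglik - null$loglik)
  if (stat < -1e-8)
    abort_validation("negative LR statistic: models not nested or not converged")
  stat <- max(stat, 0)
  df <- full$k - null$k
  p <- if (df <= 0) {
    if (stat < 1e-8) 1 else NA_real_
  } else pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' @export
print.zinb_fit <- function(x, ...) {
  cat("<zinb_fit> family=", x$family, " alpha=", format(x$alpha),
      " lambda=", format(x$lambda, digits = 4),
      "\n  loglik=", format(x$loglik, digits = 8),
      " AIC=", format(x$aic, digits = 8),
      " theta=", format(x$params$theta, digits = 4),
      "\n  active (count part): ",
      if (length(x$active_set)) paste(x$active_set, collapse = ", ")
      else "(none)",
      "\n  EM iterations: ", x$n_em_iters,
      if (x$converged) " (converged)" else " (NOT converged)", "\n", sep = "")
  invisible(x)
}

#' Serialize a fit to JSON
#' @param fit a `zinb_fit`.
#' @param path optional output file; if omitted the JSON string is returned.
#' @return path (invisibly) or a JSON string.
#' @export
fit_to_json <- function(fit, path = NULL) {
  obj <- list(
    family = fit$family, alpha = fit$alpha, lambda = fit$lambda,
    beta0 = fit$params$beta0, beta = as.list(fit$params$beta),
    gamma0 = if (fit$family == "zinb") fit$params$gamma0 else NULL,
    gamma = if (fit$family == "zinb") as.list(fit$params$gamma) else NULL,
    theta = fit$params$theta, loglik = fit$loglik, aic = fit$aic,
    penalized_objective = fit$penalized_objective,
    active_set = fit$active_set, n_em_iters = fit$n_em_iters,
    converged = fit$converged, n = fit$n)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
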
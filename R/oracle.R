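# Brute-force reference fitter for testing: minimises the identical
# penalized objective by generic smooth optimisation, independent of the
# EM / coordinate-descent path.

#' Reference fit by generic numerical minimisation (testing oracle)
#'
#' Minimises the same penalized objective as [fit_zinb_en()] with L-BFGS-B
#' after splitting every penalized coefficient into positive and negative
#' parts (`b = b+ - b-`, `b+, b- >= 0`), which makes the l1 term smooth and
#' box-constrained. Multiple restarts (a zero start plus random starts)
#' guard against local optima. Intended for tiny instances only
#' (`p <= 5`, `n <= 50`); it is deliberately slow and shares no code with
#' the EM fitter beyond the objective definition.
#'
#' @param design a `zinb_design` (or list with `X`, `y`).
#' @param alpha,lambda elastic-net penalty.
#' @param family `"zinb"` or `"nb"`.
#' @param n_restarts random restarts in addition to the zero start.
#' @param seed seed for the restart draws.
#' @param zero_tol coefficients below this magnitude are reported as
#'   inactive.
#' @return list with `objective`, `params` ([zinb_params()]), `active_set`.
#' @export
oracle_fit <- function(design, alpha, lambda, family = c("zinb", "nb"),
                       n_restarts = 5, seed = 1, zero_tol = 1e-6) {
  family <- match.arg(family)
  d <- .as_design(design)
  X <- d$X; y <- d$y
  p <- ncol(X); n <- length(y)
  if (p > 5 || n > 50)
    abort_validation("oracle_fit is restricted to p <= 5, n <= 50")

  ltr <- log(c(1e-3, 1e6))
  unpack <- function(v) {
    beta <- v[2:(p + 1)] - v[(p + 2):(2 * p + 1)]
    if (family == "zinb") {
      gamma <- v[(2 * p + 3):(3 * p + 2)] - v[(3 * p + 3):(4 * p + 2)]
      zinb_params(beta0 = v[1], beta = beta, gamma0 = v[2 * p + 2],
                  gamma = gamma, theta = exp(v[4 * p + 3]), family = family)
    } else {
      zinb_params(beta0 = v[1], beta = beta, gamma = numeric(0),
                  theta = exp(v[2 * p + 2]), family = family)
    }
  }
  dim_v <- if (family == "zinb") 4 * p + 3 else 2 * p + 2
  # elastic-net penalty on the split parameterization: l1 uses b+ + b-
  pen_split <- function(v) {
    if (family == "zinb") {
      plus <- c(v[2:(p + 1)], v[(2 * p + 3):(3 * p + 2)])
      minus <- c(v[(p + 2):(2 * p + 1)], v[(3 * p + 3):(4 * p + 2)])
    } else {
      plus <- v[2:(p + 1)]; minus <- v[(p + 2):(2 * p + 1)]
    }
    lambda * sum(alpha * (plus + minus) + (1 - alpha) / 2 * (plus - minus)^2)
  }
  fobj <- function(v) {
    -zinb_loglik(unpack(v), d) / n + pen_split(v)
  }
  lower <- rep(0, dim_v); upper <- rep(Inf, dim_v)
  ipos <- if (family == "zinb") c(1, 2 * p + 2, dim_v) else c(1, dim_v)
  lower[ipos] <- c(rep(-50, length(ipos) - 1), ltr[1])
  upper[ipos] <- c(rep(50, length(ipos) - 1), ltr[2])

  starts <- list(rep(0, dim_v))
  starts[[1]][dim_v] <- 0  # log theta = 0
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      v <- abs(rnorm(dim_v, sd = 0.5))
      v[ipos] <- rnorm(length(ipos), sd = 0.5)
      v[dim_v] <- runif(1, -1, 2)
      starts[[r + 1]] <- v
    }
  })
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, fobj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 2000, factr = 1e2)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  params <- unpack(best$par)
  obj_raw <- -zinb_loglik(params, d) / n + .penalty(params, alpha, lambda)
  params$beta[abs(params$beta) < zero_tol] <- 0
  if (family == "zinb") params$gamma[abs(params$gamma) < zero_tol] <- 0
  obj <- -zinb_loglik(params, d) / n + .penalty(params, alpha, lambda)
  obj <- min(obj, obj_raw)  # both parameter vectors are feasible
  list(objective = obj, params = params,
       active_set = colnames(X)[params$beta != 0])
}
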
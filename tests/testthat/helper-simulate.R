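# Shared fixtures, built in code at test time.

# A standardized design with iid N(0,1) covariates and a ZINB outcome with
# constant structural-zero probability. Returns the design plus the truth.
sim_design <- function(n, p, seed, beta = NULL, beta0 = 4, theta = 2,
                       pi = 0.25) {
  if (is.null(beta)) beta <- rep(0, p)
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  eta <- beta0 + drop(X %*% beta)
  y <- ifelse(runif(n) < pi, 0, rnbinom(n, size = theta, mu = exp(eta)))
  d <- structure(list(
    X = X, y = y,
    col_info = data.frame(column = colnames(X), variable = colnames(X),
                          level = "continuous", type = "continuous",
                          standardized = FALSE, train_mean = NA_real_,
                          train_sd = NA_real_, stringsAsFactors = FALSE)),
    class = "zinb_design")
  list(design = standardize_design(d)$train, raw = d,
       beta = beta, beta0 = beta0, theta = theta, pi = pi)
}

# Small random instance for oracle-agreement checks (n <= 50, p <= 5).
tiny_instance <- function(seed) {
  set.seed(seed)
  n <- sample(30:48, 1)
  p <- sample(2:4, 1)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  X <- apply(X, 2, function(c) (c - mean(c)) / sqrt(mean((c - mean(c))^2)))
  colnames(X) <- paste0("v", 1:p)
  y <- ifelse(runif(n) < 0.3, 0,
              rnbinom(n, size = 1.5, mu = exp(2 + 0.6 * X[, 1])))
  if (all(y == 0)) y[1:5] <- 1:5
  list(X = X, y = y)
}

# A cohort data.frame + codebook with one variable of each type.
small_cohort <- function(n = 60, seed = 11) {
  specs <- list(
    covariate_spec("age", "continuous", mean = 55, sd = 9),
    covariate_spec("male", "binary", prevalence = 0.5),
    covariate_spec("family_status", "categorical",
                   levels = c("married", "alone", "widowed"),
                   probs = c(0.6, 0.3, 0.1)))
  truth <- ground_truth(beta = c(age = 0.4), gamma = c(age = -0.5),
                        beta0 = log(50), gamma0 = -0.8, theta = 1.5)
  cohort <- simulate_cohort(n, specs, truth, seed)
  list(cohort = cohort, codebook = codebook_from_specs(specs),
       specs = specs, truth = truth)
}
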
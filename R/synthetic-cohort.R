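# Synthetic cohort generation: correlated mixed-type covariates from a
# latent Gaussian per block, and a zero-inflated negative binomial outcome
# with known ground truth.

#' Declare a covariate for the synthetic generator
#'
#' Covariates sharing a `block_id` are generated from a common latent
#' standard-normal factor with loading `sqrt(block_rho)`, giving within-block
#' latent correlation `block_rho` (equicorrelation) before the marginal
#' transform. The latent value is mapped to the declared type: affine for
#' continuous variables, a quantile threshold for binary variables, and
#' quantile cut-points for categorical variables.
#'
#' @param name column name (unique within a spec list).
#' @param vtype one of `"continuous"`, `"binary"`, `"categorical"`.
#' @param mean,sd marginal moments (continuous only; `sd > 0`).
#' @param prevalence probability of a 1 (binary only, in (0, 1)).
#' @param levels,probs level labels and probabilities (categorical only;
#'   probabilities must sum to 1 within 1e-12).
#' @param block_id integer correlation-block label; `NA` for an independent
#'   covariate.
#' @param block_rho within-block latent correlation in `[0, 1)`.
#' @return an object of class `covariate_spec`.
#' @export
covariate_spec <- function(name, vtype = c("continuous", "binary", "categorical"),
                           mean = 0, sd = 1, prevalence = NULL,
                           levels = NULL, probs = NULL,
                           block_id = NA_integer_, block_rho = 0) {
  vtype <- match.arg(vtype)
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    abort_validation("covariate name must be a non-empty string")
  if (!is.na(block_rho) && (block_rho < 0 || block_rho >= 1))
    abort_validation("block_rho must lie in [0, 1) for '", name, "'")
  if (vtype == "continuous") {
    if (!is.finite(sd) || sd <= 0)
      abort_validation("continuous covariate '", name, "' needs sd > 0")
  } else if (vtype == "binary") {
    if (is.null(prevalence) || prevalence <= 0 || prevalence >= 1)
      abort_validation("binary covariate '", name,
                       "' needs prevalence in (0, 1)")
  } else {
    if (is.null(levels) || is.null(probs) || length(levels) != length(probs) ||
        length(levels) < 2)
      abort_validation("categorical covariate '", name,
                       "' needs >= 2 levels with matching probs")
    if (any(probs <= 0) || abs(sum(probs) - 1) > 1e-12)
      abort_validation("level probabilities of '", name,
                       "' must be positive and sum to 1")
    if (anyDuplicated(levels))
      abort_validation("duplicate level labels in '", name, "'")
  }
  structure(list(name = name, vtype = vtype, mean = mean, sd = sd,
                 prevalence = prevalence, levels = levels, probs = probs,
                 block_id = block_id, block_rho = block_rho),
            class = "covariate_spec")
}

#' Declare the data-generating truth for the synthetic outcome
#'
#' The outcome is drawn from the zero-inflated negative binomial model: with
#' probability `pi_i = plogis(gamma0 + z_i' gamma)` the participant is a
#' structural zero (no lesion load at all); otherwise the volume is a
#' negative binomial count with mean `mu_i = exp(beta0 + x_i' beta)` and
#' dispersion `theta` (variance `mu + mu^2 / theta`). Effects are named by
#' covariate (continuous/binary) or `"variable.level"` (categorical
#' indicator); continuous covariates enter standardized, so effect sizes are
#' on the per-SD scale.
#'
#' @param beta named numeric vector of count-part (log incidence-rate)
#'   effects; may be empty.
#' @param gamma named numeric vector of zero-part (log-odds) effects.
#' @param beta0,gamma0 intercepts.
#' @param theta NB dispersion, `> 0`.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(beta = numeric(), gamma = numeric(),
                         beta0 = 0, gamma0 = 0, theta = 1) {
  if (!is.finite(theta) || theta <= 0)
    abort_validation("theta must be a positive number")
  if (length(beta) && is.null(names(beta)))
    abort_validation("beta effects must be named")
  if (length(gamma) && is.null(names(gamma)))
    abort_validation("gamma effects must be named")
  structure(list(beta = beta, gamma = gamma, beta0 = beta0,
                 gamma0 = gamma0, theta = theta),
            class = "ground_truth")
}

#' Generate correlated mixed-type covariates
#'
#' @param n number of participants (`>= 1`).
#' @param specs non-empty list of [covariate_spec()] objects with unique
#'   names.
#' @param seed integer seed; the function is a pure function of
#'   `(n, specs, seed)` and does not disturb the caller's RNG state.
#' @return a `data.frame` with `participant_id` and one column per spec.
#' @export
generate_covariates <- function(n, specs, seed) {
  if (!is.numeric(n) || n < 1) abort_validation("n must be >= 1")
  n <- as.integer(n)
  if (!length(specs)) abort_validation("specs must be non-empty")
  nm <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(nm))
    abort_validation("duplicate covariate names: ",
                     paste(unique(nm[duplicated(nm)]), collapse = ", "))
  with_seed(seed, {
    # one shared factor per block, drawn in order of first appearance
    blocks <- unique(stats::na.omit(vapply(specs, function(s)
      as.integer(s$block_id), integer(1))))
    factors <- lapply(blocks, function(b) rnorm(n))
    names(factors) <- as.character(blocks)
    cols <- lapply(specs, function(s) {
      rho <- if (is.na(s$block_id)) 0 else s$block_rho
      g <- if (is.na(s$block_id)) 0 else factors[[as.character(s$block_id)]]
      l <- sqrt(rho) * g + sqrt(1 - rho) * rnorm(n)
      switch(s$vtype,
        continuous = s$mean + s$sd * l,
        binary = as.integer(l <= qnorm(s$prevalence)),
        categorical = {
          cum <- cumsum(s$probs)
          idx <- findInterval(pnorm(l), cum, left.open = TRUE) + 1L
          s$levels[pmin(idx, length(s$levels))]
        })
    })
    names(cols) <- nm
    cbind(data.frame(participant_id = sprintf("P%05d", seq_len(n)),
                     stringsAsFactors = FALSE),
          as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE))
  })
}

# Resolve a truth effect name against the covariate table: either a column
# name (continuous / binary) or "column.level" for a categorical indicator.
# Returns the numeric column the effect multiplies (continuous standardized
# by its population moments in `tab`).
.effect_column <- function(name, tab) {
  if (name %in% names(tab)) {
    x <- tab[[name]]
    if (is.character(x) || is.factor(x))
      abort_validation("effect '", name, "' names a categorical variable; ",
                       "use 'variable.level'")
    x <- as.numeric(x)
    if (all(x %in% c(0, 1))) return(x)          # binary, enters raw
    mu <- mean(x); s <- sqrt(mean((x - mu)^2))  # continuous, per-SD scale
    if (s == 0) abort_validation("constant covariate '", name, "'")
    return((x - mu) / s)
  }
  cand <- names(tab)[startsWith(name, paste0(names(tab), "."))]
  if (length(cand)) {
    col <- cand[which.max(nchar(cand))]
    lev <- substring(name, nchar(col) + 2)
    return(as.numeric(tab[[col]] == lev))
  }
  abort_validation("ground truth references unknown variable '", name, "'")
}

.truth_linpred <- function(tab, intercept, effects) {
  eta <- rep(intercept, nrow(tab))
  for (nm in names(effects)) eta <- eta + effects[[nm]] * .effect_column(nm, tab)
  eta
}

#' Draw the zero-inflated negative binomial outcome
#'
#' Adds a `wmh_volume_mm3` column of non-negative integer volumes generated
#' under the model described in [ground_truth()].
#'
#' @param covariates a covariate table from [generate_covariates()].
#' @param truth a [ground_truth()] object.
#' @param seed integer seed.
#' @return the input table with a `wmh_volume_mm3` column appended.
#' @export
generate_outcome <- function(covariates, truth, seed) {
  stopifnot(inherits(truth, "ground_truth"))
  eta_mu <- pmin(.truth_linpred(covariates, truth$beta0, truth$beta), 30)
  eta_pi <- .truth_linpred(covariates, truth$gamma0, truth$gamma)
  pi <- plogis(eta_pi)
  mu <- exp(eta_mu)
  n <- nrow(covariates)
  with_seed(seed, {
    structural <- runif(n) < pi
    counts <- rnbinom(n, size = truth$theta, mu = mu)
    y <- ifelse(structural, 0, counts)
    covariates$wmh_volume_mm3 <- if (max(y) < .Machine$integer.max)
      as.integer(y) else y
    covariates
  })
}

#' Simulate a full cohort table with exclusion flags
#'
#' Convenience wrapper: covariates, outcome, and all five exclusion flags
#' (initialized to `FALSE`).
#'
#' @param n cohort size.
#' @param specs list of [covariate_spec()].
#' @param truth a [ground_truth()].
#' @param seed integer seed.
#' @return a cohort `data.frame`.
#' @export
simulate_cohort <- function(n, specs, truth, seed) {
  tab <- generate_covariates(n, specs, derive_seed(seed, "covariates"))
  tab <- generate_outcome(tab, truth, derive_seed(seed, "outcome"))
  for (f in EXCLUSION_FLAGS) tab[[paste0("flag_", f)]] <- FALSE
  # keep flags next to the id, covariates and outcome after
  tab[, c("participant_id", paste0("flag_", EXCLUSION_FLAGS),
          setdiff(names(tab), c("participant_id", "wmh_volume_mm3",
                                paste0("flag_", EXCLUSION_FLAGS))),
          "wmh_volume_mm3")]
}

#' Packaged KORA-like exclusion fixture
#'
#' A 400-participant cohort generated from the `kora_like` scenario with
#' disjoint exclusion-flag sets of sizes 12 (insufficient MRI quality),
#' 2 (lesions of other aetiology) and 16 (missing covariate data), mirroring
#' the discovery cohort's participant flow; after applying those three
#' exclusions 370 participants remain. Rows flagged for missing covariates
#' have the `visceral_fat` cell set to `NA`; all other rows are fully
#' populated.
#'
#' @param seed integer seed.
#' @return a cohort `data.frame` with 400 rows.
#' @export
make_kora_like_fixture <- function(seed = 1) {
  sc <- scenario_kora_like()
  tab <- simulate_cohort(sc$n, sc$specs, sc$truth, derive_seed(seed, "kora_fix"))
  idx <- with_seed(derive_seed(seed, "kora_fix", "flags"),
                   sample(nrow(tab), 12 + 2 + 16))
  tab$flag_insufficient_quality[idx[1:12]] <- TRUE
  tab$flag_other_aetiology[idx[13:14]] <- TRUE
  tab$flag_missing_covariates[idx[15:30]] <- TRUE
  tab$visceral_fat[idx[15:30]] <- NA_real_
  tab
}

#' Build the codebook for a list of covariate specs
#'
#' @param specs list of [covariate_spec()].
#' @return a `data.frame` with columns `name`, `vtype`, `levels`
#'   (semicolon-separated, empty for non-categorical) and `block_id`.
#' @export
codebook_from_specs <- function(specs) {
  data.frame(
    name = vapply(specs, function(s) s$name, character(1)),
    vtype = vapply(specs, function(s) s$vtype, character(1)),
    levels = vapply(specs, function(s)
      if (s$vtype == "categorical") paste(s$levels, collapse = ";") else "",
      character(1)),
    block_id = vapply(specs, function(s) as.integer(s$block_id), integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Serialize a ground truth to JSON
#' @param truth a [ground_truth()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
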
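# The discovery procedure: repeated 90/10 train/test splits, per-split
# cross-validated lambda tuning over two lambda_max caps, selection-frequency
# ranking and null-model comparison.

#' Generate a reproducible scheme of train/test splits
#'
#' Each split is an independent random division into `1 - test_fraction`
#' training and `test_fraction` testing rows (`|test| = round(tf * n)`).
#' Split `s` draws from its own RNG stream derived from `(seed, s)`, so the
#' scheme — and everything downstream — is invariant to processing order.
#'
#' @param n number of rows.
#' @param n_splits number of splits.
#' @param test_fraction in `(0, 0.5)`; the standard configuration is 0.1.
#' @param seed master seed.
#' @return an object of class `split_scheme`.
#' @export
make_splits <- function(n, n_splits, test_fraction = 0.1, seed = 1) {
  if (n < 20) abort_validation("need n >= 20 for splitting")
  if (test_fraction <= 0 || test_fraction >= 0.5)
    abort_validation("test_fraction must be in (0, 0.5)")
  n_test <- round(test_fraction * n)
  if (n_test < 1) abort_validation("test fraction leaves no test rows")
  splits <- lapply(seq_len(n_splits), function(s) {
    test <- sort(with_seed(derive_seed(seed, "split", s), sample(n, n_test)))
    list(train = setdiff(seq_len(n), test), test = test)
  })
  structure(list(n = as.integer(n), n_splits = as.integer(n_splits),
                 test_fraction = test_fraction,
                 seed = seed, splits = splits), class = "split_scheme")
}

#' Choose lambda (and the path cap) by ten-fold cross-validation
#'
#' For each cap fraction (0.5 and 0.1 of `lambda_max` by default) a
#' log-spaced path is built and the mean held-out log-likelihood per lambda
#' is computed over `k_folds` folds of the training data; the `(lambda, cap)`
#' pair maximising it is returned. Held-out log-likelihood (deviance) rather
#' than RMSE is used as the tuning criterion: it is the standard choice for
#' count models and also exercises the zero part. Folds whose training rows
#' have an all-zero outcome under the NB family are skipped with a warning.
#'
#' @param train a standardized training `zinb_design`.
#' @param alpha elastic-net mixing.
#' @param caps candidate upper-threshold fractions of `lambda_max`.
#' @param k_folds number of CV folds.
#' @param n_lambda path length per cap.
#' @param seed seed for the fold assignment.
#' @param family `"zinb"` or `"nb"`.
#' @param rule `"1se"` (default) returns the largest lambda whose mean
#'   held-out log-likelihood is within one standard error of the best —
#'   the standard parsimony rule when cross-validation tunes a selection
#'   procedure; `"min"` returns the maximiser itself.
#' @param controls see [zinb_controls()].
#' @return list with `lambda`, `cap`, `lam_max`, and the CV table
#'   (`cv_curve`).
#' @export
cv_select_lambda <- function(train, alpha, caps = c(0.5, 0.1), k_folds = 10,
                             n_lambda = 20, seed = 1,
                             family = c("zinb", "nb"),
                             rule = c("1se", "min"),
                             controls = zinb_controls()) {
  family <- match.arg(family)
  rule <- match.arg(rule)
  d <- .as_design(train)
  n <- length(d$y)
  if (n < k_folds) abort_validation("fewer training rows than folds")
  lam_max <- compute_lambda_max(d, alpha, family, controls)
  paths <- lapply(caps, function(cf) build_lambda_path(lam_max, cf, n_lambda))
  folds <- with_seed(derive_seed(seed, "cvfolds"),
                     sample(rep(seq_len(k_folds), length.out = n)))
  # held-out loglik, rows = lambda index, cols = fold, one matrix per cap
  cv <- lapply(paths, function(p) matrix(NA_real_, length(p), k_folds))
  for (f in seq_len(k_folds)) {
    tr <- design_rows(d, folds != f)
    te <- design_rows(d, folds == f)
    if (family == "nb" && all(tr$y == 0)) {
      warning("fold ", f, " skipped: all-zero outcome in NB training fold")
      next
    }
    for (ci in seq_along(caps)) {
      fits <- fit_zinb_path(tr, alpha, paths[[ci]], family, controls)
      cv[[ci]][, f] <- vapply(fits, function(ft)
        zinb_loglik(ft$params, te) / length(te$y), numeric(1))
    }
  }
  if (all(is.na(cv[[1]]))) abort_validation("all CV folds were skipped")
  curve <- do.call(rbind, lapply(seq_along(caps), function(ci) {
    m <- cv[[ci]]
    k_ok <- rowSums(!is.na(m))
    data.frame(cap = caps[ci], lambda = paths[[ci]],
               mean_heldout_loglik = rowMeans(m, na.rm = TRUE),
               se_heldout_loglik = apply(m, 1, sd, na.rm = TRUE) /
                 sqrt(pmax(k_ok, 1)))
  }))
  ok <- is.finite(curve$mean_heldout_loglik)
  if (!any(ok)) abort_validation("cross-validation produced no finite values")
  ibest <- which(ok)[which.max(curve$mean_heldout_loglik[ok])]
  if (rule == "1se") {
    floor_ll <- curve$mean_heldout_loglik[ibest] -
      curve$se_heldout_loglik[ibest]
    cand <- which(ok & curve$mean_heldout_loglik >= floor_ll)
    ibest <- cand[which.max(curve$lambda[cand])]
  }
  list(lambda = curve$lambda[ibest], cap = curve$cap[ibest],
       lam_max = lam_max, cv_curve = curve, rule = rule)
}

#' Stability selection over repeated train/test splits
#'
#' The core discovery procedure: for every split and every `alpha` on the
#' grid, continuous covariates are standardized with the training rows'
#' statistics, lambda is tuned by ten-fold CV with the two path caps, the
#' penalized model is fitted on the training rows, and the count-part active
#' set, test RMSE and train AIC are recorded. A variable counts as selected
#' in a split when its count-part coefficient is nonzero (exactly — the
#' coordinate-descent solutions are hard zeros). `best_alpha` minimises the
#' mean test RMSE (mean train AIC breaks ties); selection frequencies and
#' mean-beta-over-selected-splits are reported at `best_alpha`, with the full
#' per-alpha tables retained.
#'
#' @param cohort cohort `data.frame` (already past the exclusion flow), or
#'   `NULL` when `design` is given.
#' @param codebook codebook `data.frame` (with `cohort`).
#' @param scheme a [make_splits()] scheme (its `n` must match the data).
#' @param alpha_grid numeric vector of alpha values; the default grid is
#'   `c(0.01, seq(0.1, 1, by = 0.1))`.
#' @param family `"zinb"` or `"nb"`.
#' @param design optionally a prebuilt, unstandardized `zinb_design` (used
#'   by the replication stage); overrides `cohort`/`codebook`.
#' @param caps,k_folds,n_lambda,rule tuning configuration (see
#'   [cv_select_lambda()]).
#' @param aggregate `"mean"` or `"median"` aggregation of per-split RMSE/AIC.
#' @param controls see [zinb_controls()].
#' @param max_nonconverged_frac error if more than this fraction of split
#'   fits fail to converge.
#' @return an object of class `stability_result`.
#' @export
run_stability <- function(cohort = NULL, codebook = NULL, scheme,
                          alpha_grid = c(0.01, seq(0.1, 1, by = 0.1)),
                          family = c("zinb", "nb"), design = NULL,
                          caps = c(0.5, 0.1), k_folds = 10, n_lambda = 20,
                          rule = c("1se", "min"),
                          aggregate = c("mean", "median"),
                          controls = zinb_controls(),
                          max_nonconverged_frac = 0.1) {
  family <- match.arg(family)
  rule <- match.arg(rule)
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(scheme, "split_scheme"))
  if (is.null(design)) design <- encode_design(cohort, codebook)
  if (scheme$n != length(design$y))
    abort_validation("split scheme n (", scheme$n,
                     ") does not match data rows (", length(design$y), ")")
  p <- ncol(design$X)
  vars <- colnames(design$X)
  agg_fun <- if (aggregate == "mean") mean else median

  per_alpha <- list()
  for (a in alpha_grid) {
    betas <- matrix(0, scheme$n_splits, p, dimnames = list(NULL, vars))
    split_stats <- data.frame(split = seq_len(scheme$n_splits),
                              test_rmse = NA_real_, train_aic = NA_real_,
                              lambda = NA_real_, cap = NA_real_,
                              converged = NA)
    for (s in seq_len(scheme$n_splits)) {
      sp <- scheme$splits[[s]]
      std <- standardize_design(design_rows(design, sp$train),
                                design_rows(design, sp$test))
      # CV seed hashes the split's test set (not its index), so per-split
      # results — and their aggregates — are invariant to split order
      sel <- cv_select_lambda(std$train, a, caps = caps, k_folds = k_folds,
                              n_lambda = n_lambda,
                              seed = derive_seed(scheme$seed, "cv",
                                                 paste(sp$test, collapse = "-")),
                              family = family, rule = rule,
                              controls = controls)
      fit <- fit_zinb_en(std$train, a, sel$lambda, family, controls)
      betas[s, ] <- fit$params$beta
      split_stats$test_rmse[s] <- rmse(
        predict_expected_volume(fit, std$test), std$test$y)
      split_stats$train_aic[s] <- fit$aic
      split_stats$lambda[s] <- sel$lambda
      split_stats$cap[s] <- sel$cap
      split_stats$converged[s] <- fit$converged
    }
    nonconv <- mean(!split_stats$converged)
    if (nonconv > max_nonconverged_frac)
      stop(sprintf(paste0("%.0f%% of split fits did not converge ",
                          "(alpha = %g); consider increasing max_em_iters ",
                          "or loosening em_tol"), 100 * nonconv, a))
    selected <- betas != 0
    freq <- colMeans(selected)
    mean_beta <- ifelse(colSums(selected) > 0,
                        colSums(betas) / pmax(colSums(selected), 1), NA_real_)
    per_alpha[[format(a)]] <- list(
      alpha = a,
      table = data.frame(variable = vars, frequency = unname(freq),
                         mean_beta_selected = unname(mean_beta),
                         stringsAsFactors = FALSE),
      splits = split_stats,
      agg_test_rmse = agg_fun(split_stats$test_rmse),
      agg_train_aic = agg_fun(split_stats$train_aic))
  }
  rmses <- vapply(per_alpha, `[[`, numeric(1), "agg_test_rmse")
  aics <- vapply(per_alpha, `[[`, numeric(1), "agg_train_aic")
  best <- order(rmses, aics)[1]
  structure(list(
    alpha_grid = alpha_grid,
    best_alpha = per_alpha[[best]]$alpha,
    table = per_alpha[[best]]$table,
    per_alpha = per_alpha,
    n_splits_completed = scheme$n_splits,
    family = family, caps = caps, k_folds = k_folds, n_lambda = n_lambda,
    rule = rule, aggregate = aggregate, seed = scheme$seed,
    test_fraction = scheme$test_fraction), class = "stability_result")
}

#' Rank variables by selection frequency
#'
#' Descending selection frequency; ties are broken by larger
#' `|mean_beta_selected|`, then lexicographic variable name.
#'
#' @param res a `stability_result`, or a `data.frame` with columns
#'   `variable`, `frequency`, `mean_beta_selected`.
#' @param k how many variables to return (`<=` number of variables).
#' @return the top-`k` rows, ordered.
#' @export
rank_variables <- function(res, k = 10) {
  tab <- if (inherits(res, "stability_result")) res$table else res
  stopifnot(all(c("variable", "frequency", "mean_beta_selected") %in%
                  names(tab)))
  if (k > nrow(tab)) abort_validation("k exceeds the number of variables")
  mb <- abs(tab$mean_beta_selected)
  mb[is.na(mb)] <- 0
  ord <- order(-tab$frequency, -mb, tab$variable)
  out <- tab[ord[seq_len(k)], c("variable", "frequency",
                                "mean_beta_selected")]
  rownames(out) <- NULL
  out
}

#' Compare a tuned model against the intercept-only null
#'
#' Refits on the whole sample: lambda is tuned by CV at the given alpha
#' (unless `lambda` is supplied; `lambda = 0` gives the unpenalized fit),
#' and the fitted model is compared with the null model on RMSE (whole
#' sample), AIC, and a likelihood-ratio test with degrees of freedom equal
#' to the difference in lasso-df counts.
#'
#' @param design an unstandardized `zinb_design` (whole sample).
#' @param alpha elastic-net mixing for the full model.
#' @param family `"zinb"` or `"nb"`.
#' @param lambda optional fixed penalty; `NULL` tunes by CV.
#' @param seed seed for the CV folds.
#' @param caps,k_folds,n_lambda,rule tuning configuration.
#' @param controls see [zinb_controls()].
#' @return list with the two fits, `model_rmse`, `null_rmse`, `model_aic`,
#'   `null_aic`, and `lrt`.
#' @export
compare_to_null <- function(design, alpha = 1, family = c("zinb", "nb"),
                            lambda = NULL, seed = 1, caps = c(0.5, 0.1),
                            k_folds = 10, n_lambda = 20,
                            rule = c("1se", "min"),
                            controls = zinb_controls()) {
  family <- match.arg(family)
  rule <- match.arg(rule)
  std <- standardize_design(design)$train
  if (is.null(lambda)) {
    sel <- cv_select_lambda(std, alpha, caps = caps, k_folds = k_folds,
                            n_lambda = n_lambda,
                            seed = derive_seed(seed, "null_cmp"),
                            family = family, rule = rule,
                            controls = controls)
    lambda <- sel$lambda
  }
  fit <- fit_zinb_en(std, alpha, lambda, family, controls)
  null <- fit_null(std$y, family, controls)
  list(fit = fit, null = null,
       model_rmse = rmse(predict_expected_volume(fit, std), std$y),
       null_rmse = rmse(rep(mean(std$y), length(std$y)), std$y),
       model_aic = fit$aic, null_aic = null$aic,
       lrt = likelihood_ratio_test(fit, null))
}

#' @export
print.stability_result <- function(x, ...) {
  cat("<stability_result> family=", x$family, ", ",
      x$n_splits_completed, " splits, alpha grid {",
      paste(format(x$alpha_grid), collapse = ", "), "}\n",
      "best alpha = ", format(x$best_alpha), "\n", sep = "")
  print(utils::head(rank_variables(x, min(10, nrow(x$table))), 10))
  invisible(x)
}

#' Serialize a stability result to JSON
#'
#' Deterministic given the run configuration: identical configurations
#' produce byte-identical JSON.
#'
#' @param res a `stability_result`.
#' @param path optional output file.
#' @return path (invisibly) or a JSON string.
#' @export
stability_to_json <- function(res, path = NULL) {
  obj <- list(
    alpha_grid = res$alpha_grid, best_alpha = res$best_alpha,
    family = res$family, caps = res$caps, k_folds = res$k_folds,
    n_lambda = res$n_lambda, rule = res$rule, aggregate = res$aggregate,
    seed = res$seed,
    test_fraction = res$test_fraction,
    n_splits_completed = res$n_splits_completed,
    table = res$table,
    per_alpha = lapply(res$per_alpha, function(a)
      list(alpha = a$alpha, table = a$table, splits = a$splits,
           agg_test_rmse = a$agg_test_rmse, agg_train_aic = a$agg_train_aic)))
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null"))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              na = "null"), path)
  invisible(path)
}
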
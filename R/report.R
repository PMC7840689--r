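# Descriptive reporting and run configuration.

#' Descriptive summary of a cohort table
#'
#' Continuous covariates: mean, SD, median and quartiles (linear
#' interpolation, quantile type 7). Binary and categorical covariates:
#' counts and percentages per level. The outcome is summarised both ways
#' (mean +- SD and median with quartiles), as is conventional for skewed
#' volumes.
#'
#' @param cohort cohort `data.frame`.
#' @param codebook codebook `data.frame`.
#' @param outcome outcome column name.
#' @return a tidy `data.frame` with one row per variable (continuous) or per
#'   level (categorical/binary).
#' @export
describe_cohort <- function(cohort, codebook, outcome = "wmh_volume_mm3") {
  if (!nrow(cohort)) abort_validation("empty cohort")
  cont_row <- function(nm, x) {
    x <- x[!is.na(x)]
    q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
    data.frame(variable = nm, level = NA, n = length(x), mean = mean(x),
               sd = sd(x), median = q[2], q1 = q[1], q3 = q[3],
               count = NA, percent = NA,
               summary = sprintf("%.1f ± %.1f; %.1f [%.1f, %.1f]",
                                 mean(x), sd(x), q[2], q[1], q[3]),
               stringsAsFactors = FALSE)
  }
  cat_rows <- function(nm, x, levels) {
    x <- x[!is.na(x)]
    do.call(rbind, lapply(levels, function(l) {
      cnt <- sum(x == l)
      data.frame(variable = nm, level = as.character(l), n = length(x),
                 mean = NA, sd = NA, median = NA, q1 = NA, q3 = NA,
                 count = cnt, percent = 100 * cnt / length(x),
                 summary = sprintf("%d (%.1f%%)", cnt, 100 * cnt / length(x)),
                 stringsAsFactors = FALSE)
    }))
  }
  out <- list()
  for (i in seq_len(nrow(codebook))) {
    nm <- codebook$name[i]
    x <- cohort[[nm]]
    out[[nm]] <- switch(codebook$vtype[i],
      continuous = cont_row(nm, x),
      binary = cat_rows(nm, x, c(1, 0)),
      categorical = cat_rows(nm, x,
        strsplit(codebook$levels[i], ";", fixed = TRUE)[[1]]))
  }
  out[[outcome]] <- cont_row(outcome, cohort[[outcome]])
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Categorize volumes into half-open bins
#'
#' Counts of `y` in the bins `[edges[i], edges[i+1])`. Every value must fall
#' inside the overall range (use `Inf` as the last edge for an open-ended
#' top bin), so the counts always sum to `length(y)`.
#'
#' @param y non-negative numeric vector (may be empty).
#' @param edges strictly increasing bin edges.
#' @return named integer vector of counts, one per bin.
#' @export
categorize_volumes <- function(y, edges = c(0, 1, 10, 100, 1000, 1e4, Inf)) {
  if (length(edges) < 2 || is.unsorted(edges, strictly = TRUE))
    abort_validation("edges must be strictly increasing")
  if (length(y) && (any(y < edges[1]) || any(y >= edges[length(edges)])))
    abort_validation("values outside the binning range")
  idx <- findInterval(y, edges)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  names(counts) <- paste0("[", edges[-length(edges)], ",", edges[-1], ")")
  counts
}

#' Assemble and validate a pipeline run configuration
#'
#' One validated object holds every tunable of a pipeline run; it is
#' serialized alongside the results for provenance, and all randomness flows
#' from its single `seed` (stage seeds are derived with [derive_seed()]).
#'
#' @param cohort,codebook,out paths (may be `NULL` for in-memory use).
#' @param family `"zinb"` or `"nb"`.
#' @param alpha_grid alpha grid.
#' @param n_splits,test_fraction,k_folds,caps,n_lambda,top_k pipeline
#'   settings.
#' @param seed master seed.
#' @param mapping path to a YAML name-mapping file, or a named character
#'   vector.
#' @param include,exclude optional covariate include/exclude lists applied
#'   before encoding (supports sensitivity re-runs with a different panel).
#' @return an object of class `run_config`.
#' @export
run_config <- function(cohort = NULL, codebook = NULL, out = NULL,
                       family = "zinb",
                       alpha_grid = c(0.01, seq(0.1, 1, by = 0.1)),
                       n_splits = 1000, test_fraction = 0.1, k_folds = 10,
                       caps = c(0.5, 0.1), n_lambda = 20, top_k = 10,
                       seed = 1, mapping = NULL,
                       include = NULL, exclude = NULL) {
  if (!family %in% c("zinb", "nb")) abort_validation("unknown family")
  if (any(alpha_grid <= 0 | alpha_grid > 1))
    abort_validation("alpha_grid values must be in (0, 1]")
  if (test_fraction <= 0 || test_fraction >= 0.5)
    abort_validation("test_fraction must be in (0, 0.5)")
  if (n_splits < 1 || k_folds < 2 || n_lambda < 2 || top_k < 1)
    abort_validation("invalid pipeline sizes")
  structure(list(cohort = cohort, codebook = codebook, out = out,
                 family = family, alpha_grid = alpha_grid,
                 n_splits = as.integer(n_splits),
                 test_fraction = test_fraction, k_folds = as.integer(k_folds),
                 caps = caps, n_lambda = as.integer(n_lambda),
                 top_k = as.integer(top_k), seed = as.integer(seed),
                 mapping = mapping, include = include, exclude = exclude),
            class = "run_config")
}

#' Write a run configuration next to its results
#' @param config a [run_config()].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

# Restrict a codebook by include/exclude lists (sensitivity re-runs).
filter_codebook <- function(codebook, include = NULL, exclude = NULL) {
  if (!is.null(include)) {
    miss <- setdiff(include, codebook$name)
    if (length(miss))
      abort_validation("include list names unknown covariate(s): ",
                       paste(miss, collapse = ", "))
    codebook <- codebook[codebook$name %in% include, , drop = FALSE]
  }
  if (!is.null(exclude))
    codebook <- codebook[!codebook$name %in% exclude, , drop = FALSE]
  if (!nrow(codebook)) abort_validation("no covariates left after filtering")
  codebook
}
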
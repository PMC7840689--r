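# Cohort and codebook I/O, exclusion flow, design-matrix encoding and
# standardization.

#' Exclusion flags recognized in cohort tables
#' @export
EXCLUSION_FLAGS <- c("insufficient_quality", "other_aetiology",
                     "missing_covariates", "cvd_history", "age_out_of_range")

#' Write / read a cohort CSV
#'
#' The on-disk layout is: `participant_id`, the `flag_*` exclusion columns,
#' covariates as declared in the codebook, `wmh_volume_mm3`. Missing values
#' are encoded as empty cells; UTF-8 with a header row.
#'
#' @param cohort a cohort `data.frame`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @param codebook a codebook `data.frame` (see [codebook_from_specs()]).
#' @export
write_codebook <- function(codebook, path) {
  write.csv(codebook, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_codebook <- function(path) {
  cb <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                 colClasses = "character")
  need <- c("name", "vtype")
  if (!all(need %in% names(cb)))
    abort_validation("codebook must have columns 'name' and 'vtype'")
  if (is.null(cb$levels)) cb$levels <- ""
  cb$levels[is.na(cb$levels)] <- ""
  cb$block_id <- suppressWarnings(as.integer(cb$block_id %||% NA))
  cb
}

#' Read and validate a cohort table against its codebook
#'
#' Types every covariate per the codebook, rounds the outcome half-up to
#' integer mm^3 (the count model requires non-negative integers), and sets
#' the `missing_covariates` flag on any row with an empty covariate cell.
#' Exclusion-flag columns absent from the file default to `FALSE`.
#'
#' @param cohort_csv path to the cohort CSV.
#' @param codebook either a path to the codebook CSV or a codebook
#'   `data.frame`.
#' @return a validated cohort `data.frame`.
#' @export
read_cohort <- function(cohort_csv, codebook) {
  if (is.character(codebook)) codebook <- read_codebook(codebook)
  raw <- read.csv(cohort_csv, stringsAsFactors = FALSE,
                  fileEncoding = "UTF-8", colClasses = "character")
  validate_cohort(raw, codebook, context = cohort_csv)
}

#' Validate (and type) an in-memory cohort table
#'
#' @param tab cohort `data.frame` (columns may still be character).
#' @param codebook codebook `data.frame`.
#' @param context label used in error messages.
#' @return the typed, validated table.
#' @export
validate_cohort <- function(tab, codebook, context = "cohort") {
  if (!"participant_id" %in% names(tab))
    abort_validation(context, ": missing 'participant_id' column")
  tab$participant_id <- as.character(tab$participant_id)
  dup <- tab$participant_id[duplicated(tab$participant_id)]
  if (length(dup))
    abort_validation(context, ": duplicate participant IDs: ",
                     paste(unique(dup), collapse = ", "))
  if (!"wmh_volume_mm3" %in% names(tab))
    abort_validation(context, ": missing 'wmh_volume_mm3' column")
  y <- suppressWarnings(as.numeric(tab$wmh_volume_mm3))
  bad <- which(is.na(y) | y < 0)
  if (length(bad))
    abort_validation(context, ": non-numeric or negative wmh_volume_mm3 in ",
                     "row(s) ", paste(head(bad, 5), collapse = ", "))
  tab$wmh_volume_mm3 <- as.integer(round_half_up(y))

  flag_cols <- paste0("flag_", EXCLUSION_FLAGS)
  for (fc in flag_cols) {
    if (fc %in% names(tab)) {
      v <- tab[[fc]]
      tab[[fc]] <- if (is.logical(v)) v else as.character(v) %in%
        c("TRUE", "true", "1", "T")
    } else tab[[fc]] <- FALSE
  }

  declared <- codebook$name
  extra <- setdiff(names(tab),
                   c("participant_id", "wmh_volume_mm3", flag_cols, declared))
  if (length(extra))
    abort_validation(context, ": covariate column(s) not in codebook: ",
                     paste(extra, collapse = ", "))
  missing_cols <- setdiff(declared, names(tab))
  if (length(missing_cols))
    abort_validation(context, ": codebook covariate(s) absent from table: ",
                     paste(missing_cols, collapse = ", "))

  any_missing <- rep(FALSE, nrow(tab))
  for (i in seq_len(nrow(codebook))) {
    nm <- codebook$name[i]
    v <- tab[[nm]]
    if (is.character(v)) v[!nzchar(v)] <- NA
    if (codebook$vtype[i] %in% c("continuous", "binary")) {
      num <- suppressWarnings(as.numeric(v))
      conv_bad <- which(!is.na(v) & is.na(num))
      if (length(conv_bad))
        abort_validation(context, ": non-numeric value in column '", nm,
                         "', row(s) ", paste(head(conv_bad, 5), collapse = ", "))
      tab[[nm]] <- num
    } else {
      tab[[nm]] <- as.character(v)
    }
    any_missing <- any_missing | is.na(tab[[nm]])
  }
  tab$flag_missing_covariates <- tab$flag_missing_covariates | any_missing
  tab[, c("participant_id", flag_cols, declared, "wmh_volume_mm3")]
}

#' Apply the exclusion flow
#'
#' Removes every row with any listed flag set. The removal report attributes
#' each excluded row to the FIRST matching flag in `criteria` order
#' (sequential accounting, as in a participant flow diagram), so the counts
#' always sum to the number of rows removed even when flags overlap.
#'
#' @param cohort a cohort `data.frame`.
#' @param criteria ordered character vector of flag names (without the
#'   `flag_` prefix), a subset of [EXCLUSION_FLAGS].
#' @return a list with `cohort` (surviving rows) and `report` (named integer
#'   vector of removal counts in `criteria` order).
#' @export
apply_exclusions <- function(cohort, criteria = c("insufficient_quality",
                                                  "other_aetiology",
                                                  "missing_covariates")) {
  unknown <- setdiff(criteria, EXCLUSION_FLAGS)
  if (length(unknown))
    abort_validation("unknown exclusion flag(s): ",
                     paste(unknown, collapse = ", "))
  flag_mat <- vapply(criteria, function(f) {
    col <- paste0("flag_", f)
    if (col %in% names(cohort)) as.logical(cohort[[col]])
    else rep(FALSE, nrow(cohort))
  }, logical(nrow(cohort)))
  flag_mat <- matrix(flag_mat, nrow = nrow(cohort))
  first <- apply(flag_mat, 1, function(r) if (any(r)) which(r)[1] else 0L)
  report <- vapply(seq_along(criteria), function(k) sum(first == k), integer(1))
  names(report) <- criteria
  list(cohort = cohort[first == 0L, , drop = FALSE], report = report)
}

#' Encode a cohort into a numeric design matrix
#'
#' Continuous covariates give one column; binary covariates one 0/1 column
#' (values preserved); categorical covariates one indicator column per
#' non-reference level, named `variable.level`. The reference level is the
#' most frequent level in the table (ties broken by codebook level order),
#' so that reported predictors are the rarer, clinically marked levels.
#'
#' @param cohort cohort `data.frame` with no missing covariate values
#'   (apply the exclusion flow first).
#' @param codebook codebook `data.frame`.
#' @param outcome name of the outcome column.
#' @return an object of class `zinb_design`: list with the numeric matrix
#'   `X`, outcome `y`, and per-column metadata `col_info`.
#' @export
encode_design <- function(cohort, codebook, outcome = "wmh_volume_mm3") {
  n <- nrow(cohort)
  if (n == 0) abort_validation("cannot encode an empty cohort")
  cols <- list(); info <- list()
  for (i in seq_len(nrow(codebook))) {
    nm <- codebook$name[i]; vt <- codebook$vtype[i]
    v <- cohort[[nm]]
    if (is.null(v)) abort_validation("covariate '", nm, "' absent from cohort")
    if (anyNA(v))
      abort_validation("missing values remain in covariate '", nm,
                       "'; apply exclusions first")
    if (vt %in% c("continuous", "binary")) {
      if (vt == "binary" && !all(v %in% c(0, 1)))
        abort_validation("binary covariate '", nm, "' has values outside {0,1}")
      cols[[nm]] <- as.numeric(v)
      info[[nm]] <- data.frame(column = nm, variable = nm,
                               level = vt, type = vt,
                               stringsAsFactors = FALSE)
    } else {
      declared <- strsplit(codebook$levels[i], ";", fixed = TRUE)[[1]]
      obs <- unique(v)
      if (length(setdiff(obs, declared)))
        abort_validation("level(s) of '", nm, "' absent from codebook: ",
                         paste(setdiff(obs, declared), collapse = ", "))
      counts <- vapply(declared, function(l) sum(v == l), integer(1))
      ref <- declared[which.max(counts)]
      for (lev in setdiff(declared, ref)) {
        cn <- paste(nm, lev, sep = ".")
        cols[[cn]] <- as.numeric(v == lev)
        info[[cn]] <- data.frame(column = cn, variable = nm, level = lev,
                                 type = "indicator", stringsAsFactors = FALSE)
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  col_info <- do.call(rbind, info)
  rownames(col_info) <- NULL
  col_info$standardized <- FALSE
  col_info$train_mean <- NA_real_
  col_info$train_sd <- NA_real_
  y <- cohort[[outcome]]
  if (is.null(y)) abort_validation("outcome column '", outcome, "' not found")
  structure(list(X = X, y = as.numeric(y), col_info = col_info),
            class = "zinb_design")
}

#' Standardize continuous design columns with training-split statistics
#'
#' Continuous columns of `train` are centred and scaled to mean 0, SD 1
#' using the population convention (divide by n); indicator and binary
#' columns are left untouched. If `test` is supplied it is transformed with
#' the TRAIN means and SDs (no leakage of test statistics).
#'
#' @param train,test `zinb_design` objects (`test` may be `NULL`).
#' @return `list(train = , test = )` of standardized designs.
#' @export
standardize_design <- function(train, test = NULL) {
  stopifnot(inherits(train, "zinb_design"))
  info <- train$col_info
  cont <- which(info$type == "continuous")
  for (j in cont) {
    if (info$standardized[j]) next
    x <- train$X[, j]
    m <- mean(x)
    s <- sqrt(mean((x - m)^2))
    if (!is.finite(s) || s <= 0)
      abort_validation("zero-variance continuous column '", info$column[j],
                       "' in training data")
    train$X[, j] <- (x - m) / s
    info$standardized[j] <- TRUE
    info$train_mean[j] <- m
    info$train_sd[j] <- s
    if (!is.null(test)) test$X[, j] <- (test$X[, j] - m) / s
  }
  train$col_info <- info
  if (!is.null(test)) test$col_info <- info
  list(train = train, test = test)
}

# Row subset of a design (keeps metadata).
design_rows <- function(design, idx) {
  design$X <- design$X[idx, , drop = FALSE]
  design$y <- design$y[idx]
  design
}

# Column subset by column name (keeps y).
design_cols <- function(design, columns) {
  miss <- setdiff(columns, colnames(design$X))
  if (length(miss))
    abort_validation("design column(s) not found: ", paste(miss, collapse = ", "))
  keep <- match(columns, colnames(design$X))
  design$X <- design$X[, keep, drop = FALSE]
  design$col_info <- design$col_info[keep, , drop = FALSE]
  design
}

#' @export
print.zinb_design <- function(x, ...) {
  cat("<zinb_design> ", nrow(x$X), " rows x ", ncol(x$X), " columns; ",
      sum(x$col_info$standardized), " standardized\n", sep = "")
  invisible(x)
}
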
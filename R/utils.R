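# Shared internal helpers: seeded evaluation, seed derivation, validation.

#' Derive a reproducible child seed from a master seed and labels
#'
#' All randomness in the package flows from a single user-supplied seed;
#' stage- and split-level seeds are derived deterministically by hashing the
#' master seed together with string labels (e.g. the split index), so that
#' results do not depend on the order in which stages consume random numbers.
#'
#' @param seed master seed (integer).
#' @param ... labels (coerced to character) identifying the stage.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  s <- paste(c(format(seed), vapply(list(...), as.character, character(1))),
             collapse = "/")
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

# Evaluate `code` under `set.seed(seed)` without disturbing the caller's RNG
# state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

abort_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("zinbstab_validation_error",
                                             "error", "condition")))
}

# log(exp(a) + exp(b)) element-wise, stable.
log_add_exp <- function(a, b) {
  m <- pmax(a, b)
  m + log1p(exp(pmin(a, b) - m))
}

# Round half-up to integer (the mm^3 ingest convention; R's round() would
# round half to even).
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
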
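# lambda_max, the lambda path, and warm-started path fitting.

.fit_is_null <- function(fit) {
  length(fit$active_set) == 0 && length(fit$active_set_zero) == 0
}

#' Smallest penalty shrinking all coefficients to zero
#'
#' `lambda_max` anchors the regularization path: at (or above) it the fitted
#' model has empty active sets in both the count and zero parts. The value is
#' obtained from the Karush-Kuhn-Tucker condition at the converged
#' intercept-only fit: zero is a fixed point of the penalized EM whenever
#' `lambda * alpha` exceeds the largest absolute score component
#' `|(1/n) X' s|` of either part, where the scores are evaluated with the
#' null fit's posterior structural-zero weights. The bound is certified by
#' refitting, and `refine = TRUE` additionally runs a 20-step bisection
#' against actual refits (useful as a cross-check; the KKT value is already
#' exact for this algorithm).
#'
#' @param design a standardized `zinb_design`.
#' @param alpha elastic-net mixing, `> 0`.
#' @param family `"zinb"` or `"nb"`.
#' @param controls see [zinb_controls()].
#' @param refine run the bisection refinement.
#' @param bisect_steps bisection iterations when `refine = TRUE`.
#' @return the scalar `lambda_max`.
#' @export
compute_lambda_max <- function(design, alpha, family = c("zinb", "nb"),
                               controls = zinb_controls(), refine = FALSE,
                               bisect_steps = 20) {
  family <- match.arg(family)
  if (alpha <= 0) abort_validation("alpha must be > 0")
  d <- .as_design(design)
  X <- d$X; y <- d$y
  n <- length(y)
  if (ncol(X) == 0 || all(apply(X, 2, function(c) max(c) == min(c))))
    abort_validation("degenerate design: no varying columns")

  # the score must be evaluated at a tightly converged intercept-only fit:
  # residual drift in the intercepts or theta shifts the KKT threshold
  tight <- controls
  tight$em_tol <- min(controls$em_tol, 1e-12)
  tight$max_em_iters <- max(controls$max_em_iters, 500)
  null <- fit_null(y, family, tight)
  pnull <- .expand_params(null$params, ncol(X), family)
  z <- .estep(pnull, X, y)
  u <- 1 - z
  lp <- .linpreds(pnull, X)
  score_beta <- drop(crossprod(X, u * (y - lp$mu) * pnull$theta /
                                 (pnull$theta + lp$mu))) / n
  g <- abs(score_beta)
  if (family == "zinb") {
    pi <- plogis(lp$eta_pi)
    g <- c(g, abs(drop(crossprod(X, z - pi))) / n)
  }
  # nudge just above the knife edge: at exactly max|score|/alpha the
  # soft-threshold comparison can tip either way in floating point
  lam <- max(g) / alpha * (1 + 1e-8)

  # certify by refitting (warm from the null fixed point)
  init <- pnull
  for (k in 0:5) {
    fit <- fit_zinb_en(d, alpha, lam, family, controls, init = init)
    if (.fit_is_null(fit)) break
    lam <- lam * 2
  }
  if (!.fit_is_null(fit))
    warning("lambda_max certification failed; returning KKT bound")

  if (refine) {
    hi <- lam
    lo <- NA
    probe <- lam / 2
    while (probe > lam * 1e-3) {
      f <- fit_zinb_en(d, alpha, probe, family, controls, init = init)
      if (!.fit_is_null(f)) { lo <- probe; break }
      probe <- probe / 2
    }
    if (is.na(lo)) return(lam)  # nothing ever enters: KKT bound stands
    for (s in seq_len(bisect_steps)) {
      mid <- sqrt(lo * hi)
      f <- fit_zinb_en(d, alpha, mid, family, controls, init = init)
      if (.fit_is_null(f)) hi <- mid else lo <- mid
    }
    lam <- hi
  }
  lam
}

#' Build a decreasing log-spaced lambda path
#'
#' The path starts at `cap_fraction * lambda_max` (the tuning procedure uses
#' caps of 0.5 and 0.1) and descends log-linearly to `1e-3 * lambda_max`.
#'
#' @param lam_max the anchor from [compute_lambda_max()].
#' @param cap_fraction upper-threshold fraction in `(0, 1]`; 0.5 or 0.1 in
#'   the standard configuration.
#' @param n_lambda path length, `>= 2`.
#' @return strictly decreasing numeric vector of length `n_lambda`.
#' @export
build_lambda_path <- function(lam_max, cap_fraction, n_lambda = 20) {
  if (!is.finite(lam_max) || lam_max <= 0)
    abort_validation("lam_max must be positive")
  if (!is.finite(cap_fraction) || cap_fraction <= 0 || cap_fraction > 1)
    abort_validation("cap_fraction must be in (0, 1]")
  if (n_lambda < 2) abort_validation("n_lambda must be >= 2")
  exp(seq(log(cap_fraction * lam_max), log(1e-3 * lam_max),
          length.out = n_lambda))
}

#' Fit a model at every value of a lambda path (warm starts)
#'
#' @param design a standardized `zinb_design`.
#' @param alpha elastic-net mixing.
#' @param path decreasing lambda sequence.
#' @param family `"zinb"` or `"nb"`.
#' @param controls see [zinb_controls()].
#' @return list of `zinb_fit` objects, one per lambda.
#' @export
fit_zinb_path <- function(design, alpha, path, family = c("zinb", "nb"),
                          controls = zinb_controls()) {
  family <- match.arg(family)
  d <- .as_design(design)
  fits <- vector("list", length(path))
  init <- NULL
  for (i in seq_along(path)) {
    fits[[i]] <- fit_zinb_en(d, alpha, path[i], family, controls, init = init)
    init <- fits[[i]]$params
  }
  fits
}
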
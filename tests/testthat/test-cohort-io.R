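# Cohort I/O, the exclusion flow, design encoding and standardization.

test_that("cohort CSV round-trips exactly", {
  sc <- small_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  cbp <- withr::local_tempfile(fileext = ".csv")
  write_cohort(sc$cohort, path)
  write_codebook(sc$codebook, cbp)
  back <- read_cohort(path, cbp)
  rownames(back) <- rownames(sc$cohort) <- NULL
  expect_equal(back, sc$cohort)
})

test_that("validation errors carry row/column context", {
  sc <- small_cohort()
  tab <- sc$cohort
  tab$mystery <- 1
  expect_error(validate_cohort(tab, sc$codebook), "mystery")
  tab2 <- sc$cohort
  tab2$participant_id[2] <- tab2$participant_id[1]
  expect_error(validate_cohort(tab2, sc$codebook), "duplicate participant")
  tab3 <- sc$cohort
  tab3$wmh_volume_mm3[3] <- -1
  expect_error(validate_cohort(tab3, sc$codebook), "row")
  tab4 <- sc$cohort
  tab4$age[5] <- "not a number"
  expect_error(validate_cohort(tab4, sc$codebook), "age")
})

test_that("an empty covariate cell sets the missing_covariates flag", {
  sc <- small_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- sc$cohort
  tab$age[4] <- NA
  write_cohort(tab, path)          # NA written as empty cell
  back <- read_cohort(path, sc$codebook)
  expect_true(back$flag_missing_covariates[4])
  expect_false(any(back$flag_missing_covariates[-4]))
})

test_that("volumes are rounded half-up to integer mm3 on ingest", {
  sc <- small_cohort(n = 30)
  tab <- sc$cohort
  tab$wmh_volume_mm3 <- tab$wmh_volume_mm3 + 0.5
  out <- validate_cohort(tab, sc$codebook)
  expect_identical(out$wmh_volume_mm3, sc$cohort$wmh_volume_mm3 + 1L)
})

test_that("exclusion flow reproduces the packaged participant counts", {
  fx <- make_kora_like_fixture(seed = 1)
  res <- apply_exclusions(fx, c("insufficient_quality", "other_aetiology",
                                "missing_covariates"))
  expect_identical(nrow(res$cohort), 370L)
  expect_identical(unname(res$report), c(12L, 2L, 16L))
})

test_that("exclusion accounting is sequential and order-sensitive, the
           surviving set is not", {
  tab <- data.frame(participant_id = as.character(1:6),
                    flag_insufficient_quality = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                    flag_other_aetiology = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
                    wmh_volume_mm3 = 0:5)
  a <- apply_exclusions(tab, c("insufficient_quality", "other_aetiology"))
  b <- apply_exclusions(tab, c("other_aetiology", "insufficient_quality"))
  expect_identical(a$cohort$participant_id, b$cohort$participant_id)
  expect_identical(unname(a$report), c(2L, 1L))  # row 1 goes to the first flag
  expect_identical(unname(b$report), c(2L, 1L))
  expect_identical(sum(a$report), nrow(tab) - nrow(a$cohort))
})

test_that("exclusion edge cases: no flags, all flagged, unknown flag", {
  sc <- small_cohort(n = 25)
  res <- apply_exclusions(sc$cohort)
  expect_identical(nrow(res$cohort), 25L)
  expect_true(all(res$report == 0L))
  tab <- sc$cohort
  tab$flag_cvd_history <- TRUE
  res2 <- apply_exclusions(tab, "cvd_history")
  expect_identical(nrow(res2$cohort), 0L)
  expect_error(apply_exclusions(tab, "bogus"), "unknown exclusion flag")
})

test_that("dummy coding: levels - 1 columns, most-frequent reference", {
  cb <- data.frame(name = c("f", "b"), vtype = c("categorical", "binary"),
                   levels = c("a;b;c;d;e", ""), block_id = NA)
  set.seed(2)
  tab <- data.frame(participant_id = as.character(1:100),
                    f = sample(c(rep("a", 60), rep("b", 20), rep("c", 10),
                                 rep("d", 6), rep("e", 4))),
                    b = rep(c(0, 1), 50),
                    wmh_volume_mm3 = rpois(100, 5))
  d <- encode_design(tab, cb)
  expect_identical(ncol(d$X), 5L)  # 4 indicators + 1 binary
  expect_false("f.a" %in% colnames(d$X))  # 60% level is the reference
  expect_setequal(colnames(d$X), c("f.b", "f.c", "f.d", "f.e", "b"))
  expect_identical(d$X[, "b"], tab$b)  # binary values preserved
  expect_identical(unname(colSums(d$X[, c("f.b", "f.c", "f.d", "f.e")])),
                   c(20, 10, 6, 4))
  # undeclared level errors
  tab$f[1] <- "zzz"
  expect_error(encode_design(tab, cb), "zzz")
})

test_that("standardization uses population SD and train-only statistics", {
  mk <- function(x) structure(list(
    X = matrix(x, ncol = 1, dimnames = list(NULL, "v")),
    y = rep(1, length(x)),
    col_info = data.frame(column = "v", variable = "v", level = "continuous",
                          type = "continuous", standardized = FALSE,
                          train_mean = NA_real_, train_sd = NA_real_)),
    class = "zinb_design")
  out <- standardize_design(mk(c(0, 2)), mk(3))
  expect_equal(drop(out$train$X), c(-1, 1))   # population SD = 1
  expect_equal(unname(drop(out$test$X)), 2)   # (3 - 1) / 1
  expect_equal(out$train$col_info$train_mean, 1)
  expect_equal(out$train$col_info$train_sd, 1)
  # indicator columns are untouched
  d <- mk(c(0, 1, 1, 0))
  d$col_info$type <- "indicator"
  expect_equal(standardize_design(d)$train$X, d$X)
  # zero-variance continuous column errors with its name
  expect_error(standardize_design(mk(c(2, 2, 2))), "'v'")
})

test_that("standardizing standardized data is the identity", {
  s <- sim_design(80, 3, seed = 9, beta = c(0.3, 0, 0))
  once <- s$design
  # re-encode as a fresh unstandardized design carrying standardized values
  again <- once
  again$col_info$standardized <- FALSE
  again$col_info$train_mean <- NA_real_
  again$col_info$train_sd <- NA_real_
  twice <- standardize_design(again)$train
  expect_lt(max(abs(twice$X - once$X)), 1e-10)
})
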
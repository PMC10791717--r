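make_table <- function(n, p = 5, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  x
}

test_that("the robust scaler uses linear-interpolation quartiles and centers constants", {
  x <- cbind(a = c(1, 2, 3, 4, 5), b = c(7, 7, 7, 7, 7))
  sc <- suppressWarnings(fit_scaler(x))
  expect_equal(unname(sc$median["a"]), 3)
  expect_equal(unname(sc$q1["a"]), 2)
  expect_equal(unname(sc$q3["a"]), 4)
  xs <- apply_scaler(sc, x)
  expect_equal(unname(xs[, "a"]), c(-1, -0.5, 0, 0.5, 1))
  expect_equal(unname(xs[, "b"]), rep(0, 5))        # constant column, no error
  expect_warning(fit_scaler(x), "constant")

  # scaled training data has median 0 and IQR 1 per non-degenerate feature
  set.seed(2)
  y <- matrix(stats::rnorm(40), 20, 2, dimnames = list(NULL, c("u", "v")))
  ys <- apply_scaler(fit_scaler(y), y)
  expect_equal(unname(apply(ys, 2, stats::median)), c(0, 0))
  expect_equal(unname(apply(ys, 2, stats::IQR)), c(1, 1))

  # a test sample at the training medians scales to all zeros
  med <- matrix(apply(y, 2, stats::median), 1, dimnames = list(NULL, c("u", "v")))
  expect_equal(unname(apply_scaler(fit_scaler(y), med))[1, ], c(0, 0))
})

test_that("the penalized fit shrinks to the intercept and reduces to OLS at zero penalty", {
  x <- make_table(50, 6)
  set.seed(3)
  y <- x %*% stats::rnorm(6) + stats::rnorm(50, sd = 0.3)

  # huge penalty: every coefficient exactly zero, intercept = mean(y)
  big <- fit_lasso(x, y, alpha = 1e6)
  expect_true(all(big$coefficients == 0))
  expect_equal(big$intercept, mean(y))

  # zero penalty on a full-rank design: OLS to 1e-8
  ols <- stats::lm.fit(cbind(1, x), as.numeric(y))$coefficients
  fit0 <- fit_lasso(x, y, alpha = 0)
  expect_equal(unname(fit0$coefficients), unname(ols[-1]), tolerance = 1e-8)
  expect_lt(abs(fit0$intercept - unname(ols[1])), 1e-8)
})

test_that("the L1 path is sparse and recovers planted signal features", {
  set.seed(4)
  n <- 200; p <- 20
  x <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  active <- c("f2", "f5", "f9", "f13", "f17")
  beta <- stats::setNames(numeric(p), colnames(x))
  beta[active] <- c(3, -2.5, 2, 2.8, -3.2)
  y <- x %*% beta + stats::rnorm(n, sd = 0.5)
  fit <- fit_lasso(x, y, alpha = 1e-2)
  top5 <- names(sort(abs(fit$coefficients), decreasing = TRUE))[1:5]
  expect_setequal(top5, active)

  # total |coef| is non-increasing along increasing penalty
  alphas <- c(0, 1e-3, 1e-2, 1e-1, 1)
  l1 <- vapply(alphas, function(a) sum(abs(fit_lasso(x, y, a)$coefficients)), 0)
  expect_true(all(diff(l1) <= 1e-8))
})

test_that("prediction is the intercept plus the scaled linear term", {
  x <- make_table(30, 4)
  set.seed(5)
  y <- as.numeric(x %*% c(1, -1, 2, 0) + stats::rnorm(30, sd = 0.1))
  m <- train_pwat_model(x, y, alpha = 1e-2)

  med <- vapply(seq_len(ncol(x)), function(j) stats::median(x[, j]), 0)
  names(med) <- colnames(x)
  expect_equal(predict(m, med), m$intercept)

  # linearity on the scaled space: pred(a) + pred(b) - intercept = intercept + s(a) + s(b)
  a <- x[1, ]; b <- x[2, ]
  sa <- apply_scaler(m$scaler, matrix(a, 1, dimnames = list(NULL, names(a))))
  sb <- apply_scaler(m$scaler, matrix(b, 1, dimnames = list(NULL, names(b))))
  lhs <- predict(m, a) + predict(m, b) - m$intercept
  rhs <- m$intercept + as.numeric((sa + sb) %*% m$coefficients)
  expect_equal(lhs, rhs)

  # clamping truncates to the grading-scale range
  m0 <- m; m0$intercept <- 40
  expect_equal(predict(m0, med, clamp = TRUE), 32)

  # schema mismatch is a distinct error
  bad <- stats::setNames(as.numeric(a), paste0("g", seq_along(a)))
  expect_error(predict(m, bad), class = "pwat_schema_error")
})

test_that("Spearman correlation matches the rank-difference formula and rejects constants", {
  y <- c(3, 1, 4, 1.5, 9)
  expect_equal(spearman_rho(y, y), 1)
  expect_equal(spearman_rho(y, -y), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)),
               oracle_spearman(c(1, 2, 3, 4), c(1, 3, 2, 4)))
  expect_error(spearman_rho(rep(1, 5), y), "constant")
})

test_that("stratified folds partition the samples and respect score bins", {
  set.seed(6)
  y <- stats::rnorm(83, 15, 3)
  cv <- stratified_kfold_cv(make_table(83, 3, seed = 7), y, folds = 10, seed = 1)
  expect_equal(sort(unique(cv$fold_id)), 1:10)
  expect_equal(length(cv$fold_id), 83)
  expect_true(all(table(cv$fold_id) >= 8))   # balanced within one sample
})

test_that("a noiseless linear score is recovered with pooled rank correlation 1", {
  set.seed(8)
  x <- make_table(120, 5, seed = 8)
  y <- as.numeric(x %*% c(2, -1, 1.5, 3, -2))
  # unpenalized folds recover the map exactly: pooled rho is exactly 1
  cv0 <- stratified_kfold_cv(x, y, folds = 10, alpha = 0, seed = 0)
  expect_equal(cv0$rho, 1.0)
  # the default penalty shrinks but preserves the ranking almost perfectly
  cv <- stratified_kfold_cv(x, y, folds = 10, alpha = 1e-2, seed = 0)
  expect_gt(cv$rho, 0.999)
})

test_that("repeated CV yields one rho per repeat and repeat 1 reproduces the single CV", {
  set.seed(9)
  x <- make_table(60, 4, seed = 9)
  y <- as.numeric(x %*% c(1, 2, -1, 0.5) + stats::rnorm(60, sd = 0.5))
  single <- stratified_kfold_cv(x, y, seed = 5)
  rep1 <- repeated_cv(x, y, repeats = 1, seed = 5)
  expect_equal(rep1$rho, single$rho)
  rep5 <- repeated_cv(x, y, repeats = 5, seed = 5)
  expect_length(rep5$rho, 5)
  expect_named(rep5$summary[1:2], c("mean", "sd"))
})

test_that("multiplying a raw feature column by a positive constant leaves predictions unchanged", {
  set.seed(10)
  x <- make_table(70, 4, seed = 10)
  y <- as.numeric(x %*% c(1, -2, 0.5, 1) + stats::rnorm(70, sd = 0.3))
  cv1 <- stratified_kfold_cv(x, y, seed = 3)
  x2 <- x; x2[, 2] <- x2[, 2] * 37.5
  cv2 <- stratified_kfold_cv(x2, y, seed = 3)
  expect_equal(cv1$predictions, cv2$predictions, tolerance = 1e-8)
})

test_that("scaler and coefficients of a fold depend on its training data only", {
  set.seed(11)
  x <- make_table(60, 5, seed = 11)
  y <- as.numeric(x %*% c(1, 1, -1, 2, 0) + stats::rnorm(60, sd = 0.4))
  cv1 <- stratified_kfold_cv(x, y, folds = 5, seed = 2)
  f <- 3L
  x2 <- x
  x2[cv1$fold_id == f, ] <- x2[cv1$fold_id == f, ] + 100  # perturb fold-3 test rows
  cv2 <- stratified_kfold_cv(x2, y, folds = 5, seed = 2)
  expect_identical(cv1$fold_id, cv2$fold_id)              # folds depend on scores only
  expect_equal(cv1$coefficients[f, ], cv2$coefficients[f, ])
  expect_equal(cv1$intercepts[f], cv2$intercepts[f])
  expect_equal(unclass(cv1$scalers[[f]]), unclass(cv2$scalers[[f]]))
})

test_that("feature ranking orders by absolute averaged coefficient and flags zeros", {
  rep_fake <- list(coefficients = matrix(c(0, 2, -3), 1,
                                         dimnames = list(NULL, c("a", "b", "c"))))
  rk <- rank_features(rep_fake)
  expect_equal(rk$feature, c("c", "b", "a"))
  expect_equal(rk$informative, c(TRUE, TRUE, FALSE))

  zero <- list(coefficients = matrix(0, 3, 2, dimnames = list(NULL, c("a", "b"))))
  rkz <- rank_features(zero)
  expect_false(any(rkz$informative))
})

test_that("models round-trip through JSON", {
  x <- make_table(25, 3, seed = 12)
  set.seed(12)
  y <- as.numeric(x %*% c(1, 2, 3) + stats::rnorm(25, sd = 0.2))
  m <- train_pwat_model(x, y, alpha = 0.05, config = list(levels = 32L))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(m2$scaler$median, m$scaler$median)
  expect_equal(m2$alpha, m$alpha)
  expect_equal(predict(m2, x), predict(m, x))
})
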
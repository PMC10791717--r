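#' Fit a robust (median/IQR) scaler on training features
#'
#' Estimates, per feature, the median and the 1st and 3rd quartiles
#' (linear-interpolation quantiles). Scaling maps `x` to
#' `(x - median) / (q3 - q1)`, so the scaled training column has median 0
#' and interquartile range 1. A constant feature (`q3 == q1`) is centered
#' only, with the divisor replaced by 1 and a warning.
#'
#' @param features Feature table (data.frame or matrix; a `sample_id`
#'   column is ignored) with >= 2 rows.
#' @return Object of class `robust_scaler`: list with `median`, `q1`, `q3`,
#'   `scale` (the divisor actually used) per feature.
#' @export
fit_scaler <- function(features) {
  x <- scaler_matrix(features)
  if (nrow(x) < 2L) stop("need >= 2 training samples to fit the scaler", call. = FALSE)
  med <- apply(x, 2L, stats::median)
  q1 <- apply(x, 2L, stats::quantile, probs = 0.25, names = FALSE)
  q3 <- apply(x, 2L, stats::quantile, probs = 0.75, names = FALSE)
  iqr <- q3 - q1
  if (any(iqr == 0)) {
    warning(sprintf("%d constant feature(s): centered only (divisor 1)",
                    sum(iqr == 0)))
  }
  structure(list(median = med, q1 = q1, q3 = q3,
                 scale = ifelse(iqr == 0, 1, iqr)),
            class = "robust_scaler")
}

#' Apply a fitted robust scaler
#'
#' @param scaler A [fit_scaler()] result.
#' @param features Feature table or matrix with the same columns.
#' @return Numeric matrix of scaled features.
#' @export
apply_scaler <- function(scaler, features) {
  x <- scaler_matrix(features)
  x <- x[, names(scaler$median), drop = FALSE]
  sweep(sweep(x, 2L, scaler$median, "-"), 2L, scaler$scale, "/")
}

# Accept either the pinned 54-feature schema or any numeric table (the
# scaler/model machinery is generic over feature sets).
scaler_matrix <- function(features) {
  if (is.data.frame(features)) {
    features <- as.matrix(features[, setdiff(colnames(features), "sample_id"),
                                   drop = FALSE])
  }
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  }
  storage.mode(features) <- "double"
  features
}

#' Fit the L1-penalized (Lasso) linear model on scaled features
#'
#' Minimizes `(1/(2n)) * RSS + alpha * sum(|coef|)` with an unpenalized
#' intercept (the glmnet objective with `lambda = alpha` and no internal
#' standardization — inputs are expected to be robust-scaled already).
#' `alpha = 0` reduces to ordinary least squares.
#'
#' @param x Numeric matrix of scaled features (n x p).
#' @param y Numeric response (observed PWAT scores).
#' @param alpha Penalization coefficient (default `1e-2`).
#' @return List with `intercept`, `coefficients` (named), `alpha`.
#' @export
fit_lasso <- function(x, y, alpha = 1e-2) {
  x <- scaler_matrix(x)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values in the design or response", call. = FALSE)
  }
  if (nrow(x) < 2L) stop("need >= 2 samples", call. = FALSE)
  if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  fit <- glmnet::glmnet(x, y, family = "gaussian", alpha = 1, lambda = alpha,
                        standardize = FALSE, intercept = TRUE,
                        thresh = 1e-14, maxit = 1e7)
  beta <- as.numeric(fit$beta)
  names(beta) <- colnames(x)
  list(intercept = as.numeric(fit$a0), coefficients = beta, alpha = alpha)
}

#' Train a PWAT regression model (scaler + Lasso)
#'
#' Fits the robust scaler on the training table, scales it, and fits the
#' penalized linear model. The returned model carries the scaler, the
#' coefficients and the configuration metadata (penalty, GLCM settings) so
#' that prediction always reproduces the training-time feature pipeline.
#'
#' @param features Training feature table (data.frame with `sample_id` or
#'   plain matrix).
#' @param scores Numeric observed PWAT scores, same length as rows.
#' @param alpha Penalization coefficient (default `1e-2`).
#' @param config Named list of feature-pipeline metadata stored with the
#'   model (e.g. `levels`, `distance`, `kernel_size`).
#' @return Object of class `pwat_model`.
#' @export
train_pwat_model <- function(features, scores, alpha = 1e-2,
                             config = list(kernel_size = 3L, levels = 64L,
                                           distance = 1L)) {
  x <- scaler_matrix(features)
  if (nrow(x) != length(scores)) {
    stop("feature rows and scores differ in length", call. = FALSE)
  }
  scaler <- fit_scaler(x)
  fit <- fit_lasso(apply_scaler(scaler, x), scores, alpha = alpha)
  structure(list(scaler = scaler, intercept = fit$intercept,
                 coefficients = fit$coefficients, alpha = alpha,
                 feature_names = colnames(x), config = config,
                 format_version = 1L),
            class = "pwat_model")
}

#' Predict PWAT scores from features
#'
#' Applies the model's robust scaler and linear coefficients. Predictions
#' are continuous and unclamped by default; `clamp = TRUE` truncates them
#' to the 0-32 range of the grading scale.
#'
#' @param object A [train_pwat_model()] model.
#' @param features Feature table or named vector matching the model's
#'   feature names.
#' @param clamp Truncate predictions to \[0, 32\] (default FALSE).
#' @param ... Unused.
#' @return Numeric vector of predicted scores.
#' @export
predict.pwat_model <- function(object, features, clamp = FALSE, ...) {
  if (is.null(dim(features)) && !is.data.frame(features)) {
    features <- matrix(features, 1L, dimnames = list(NULL, names(features)))
  }
  x <- scaler_matrix(features)
  if (!setequal(colnames(x), object$feature_names)) {
    stop(structure(class = c("pwat_schema_error", "error", "condition"),
                   list(message = "feature names do not match the trained model",
                        call = NULL)))
  }
  x <- x[, object$feature_names, drop = FALSE]
  xs <- apply_scaler(object$scaler, x)
  pred <- as.numeric(object$intercept + xs %*% object$coefficients)
  if (clamp) pred <- pmin(pmax(pred, 0), 32)
  pred
}

#' Spearman rank correlation
#'
#' Rank correlation with average-rank tie handling. A constant input has no
#' defined rank correlation and raises an error.
#'
#' @param predicted,observed Numeric vectors of equal length >= 2.
#' @return A number in \[-1, 1\].
#' @export
spearman_rho <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 2L) {
    stop("need two equal-length vectors of length >= 2", call. = FALSE)
  }
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    stop("Spearman correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(predicted, observed, method = "spearman")
}

# Quantile-bin continuous scores for stratification; bins smaller than the
# fold count are merged into their neighbour.
stratify_bins <- function(scores, bins = 5L, folds = 10L) {
  breaks <- unique(stats::quantile(scores, probs = seq(0, 1, length.out = bins + 1L)))
  if (length(breaks) < 3L) return(rep(1L, length(scores)))
  b <- cut(scores, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  repeat {
    counts <- tabulate(b, nbins = max(b))
    present <- which(counts > 0L)
    small <- present[counts[present] < folds]
    if (length(small) == 0L || length(present) <= 1L) break
    s <- small[1L]
    neighbour <- if (any(present > s)) min(present[present > s]) else max(present[present < s])
    b[b == s] <- neighbour
  }
  as.integer(factor(b))
}

# Shuffled stratified fold assignment: within each score bin, samples are
# shuffled and dealt round-robin over the folds.
make_stratified_folds <- function(scores, folds = 10L, bins = 5L, seed = 0L) {
  n <- length(scores)
  if (n < folds) stop("need at least as many samples as folds", call. = FALSE)
  b <- stratify_bins(scores, bins = bins, folds = folds)
  fold_id <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (bin in sort(unique(b))) {
      idx <- sample(which(b == bin))
      fold_id[idx] <- ((seq_along(idx) - 1L + offset) %% folds) + 1L
      offset <- offset + length(idx)
    }
  })
  fold_id
}

#' One shuffled stratified k-fold cross-validation
#'
#' Bins the continuous scores into quantile bins (default 5; bins with
#' fewer members than folds are merged), deals each bin's shuffled samples
#' round-robin over the folds, and, for each fold, fits the robust scaler
#' and the penalized model on the training 90% only, predicting the held-out
#' 10%. Out-of-fold predictions are pooled and summarized by one Spearman
#' rank correlation.
#'
#' @param features Feature table (data.frame with `sample_id` or matrix).
#' @param scores Observed PWAT scores.
#' @param folds Number of folds (default 10).
#' @param bins Stratification quantile bins (default 5).
#' @param alpha Penalization coefficient (default `1e-2`).
#' @param seed Integer seed for the shuffling.
#' @return Object of class `pwat_cv`: `rho` (pooled out-of-fold Spearman),
#'   `predictions` (in input order), `fold_id`, `coefficients` (folds x p
#'   matrix), `intercepts`, `scalers` (per-fold), `mean_coefficients`.
#' @export
stratified_kfold_cv <- function(features, scores, folds = 10L, bins = 5L,
                                alpha = 1e-2, seed = 0L) {
  x <- scaler_matrix(features)
  n <- nrow(x)
  if (n != length(scores)) stop("feature rows and scores differ", call. = FALSE)
  fold_id <- make_stratified_folds(scores, folds = folds, bins = bins, seed = seed)
  pred <- numeric(n)
  coefs <- matrix(NA_real_, folds, ncol(x), dimnames = list(NULL, colnames(x)))
  intercepts <- numeric(folds)
  scalers <- vector("list", folds)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    scaler <- fit_scaler(x[!test, , drop = FALSE])
    fit <- fit_lasso(apply_scaler(scaler, x[!test, , drop = FALSE]),
                     scores[!test], alpha = alpha)
    coefs[f, ] <- fit$coefficients
    intercepts[f] <- fit$intercept
    scalers[[f]] <- scaler
    xs <- apply_scaler(scaler, x[test, , drop = FALSE])
    pred[test] <- fit$intercept + as.numeric(xs %*% fit$coefficients)
  }
  structure(list(rho = spearman_rho(pred, scores), predictions = pred,
                 fold_id = fold_id, coefficients = coefs,
                 intercepts = intercepts, scalers = scalers,
                 mean_coefficients = colMeans(coefs),
                 folds = folds, bins = bins, alpha = alpha, seed = seed),
            class = "pwat_cv")
}

#' Repeated shuffled stratified cross-validation
#'
#' Re-runs [stratified_kfold_cv()] `repeats` times with repeat seeds
#' derived deterministically from the master seed, collecting one pooled
#' out-of-fold Spearman correlation per repeat and one coefficient vector
#' per repeat (the mean over that repeat's hold-out fold models).
#'
#' @inheritParams stratified_kfold_cv
#' @param repeats Number of repeated cross-validations (default 100).
#' @return Object of class `pwat_repeated_cv`: `rho` (length `repeats`),
#'   `coefficients` (repeats x p), `summary` (mean, sd, quartiles of rho),
#'   `seeds`.
#' @export
repeated_cv <- function(features, scores, repeats = 100L, folds = 10L,
                        bins = 5L, alpha = 1e-2, seed = 0L) {
  repeats <- as.integer(repeats)
  if (repeats < 1L) stop("`repeats` must be >= 1", call. = FALSE)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, repeats))
  if (repeats >= 1L) seeds[1L] <- seed  # repeats = 1 reproduces a single CV
  rho <- numeric(repeats)
  coefs <- NULL
  for (r in seq_len(repeats)) {
    cv <- stratified_kfold_cv(features, scores, folds = folds, bins = bins,
                              alpha = alpha, seed = seeds[r])
    rho[r] <- cv$rho
    if (is.null(coefs)) {
      coefs <- matrix(NA_real_, repeats, length(cv$mean_coefficients),
                      dimnames = list(NULL, names(cv$mean_coefficients)))
    }
    coefs[r, ] <- cv$mean_coefficients
  }
  structure(list(rho = rho, coefficients = coefs,
                 summary = c(mean = mean(rho), sd = stats::sd(rho),
                             stats::quantile(rho, c(0.25, 0.5, 0.75))),
                 seeds = seeds, repeats = repeats, folds = folds,
                 bins = bins, alpha = alpha),
            class = "pwat_repeated_cv")
}

#' Rank features by averaged Lasso coefficient
#'
#' Averages the coefficient vectors across repeats and orders the features
#' by decreasing absolute mean coefficient. Features whose mean coefficient
#' is exactly zero were never selected by the penalty and are flagged
#' uninformative.
#'
#' @param report A [repeated_cv()] or [stratified_kfold_cv()] result.
#' @return data.frame `feature, mean_coefficient, abs_coefficient, rank,
#'   informative`, ordered by rank.
#' @export
rank_features <- function(report) {
  coefs <- report$coefficients
  if (is.null(coefs) || nrow(coefs) < 1L) {
    stop("report contains no coefficient vectors", call. = FALSE)
  }
  m <- colMeans(coefs)
  ord <- order(abs(m), decreasing = TRUE)
  data.frame(feature = names(m)[ord], mean_coefficient = as.numeric(m[ord]),
             abs_coefficient = abs(as.numeric(m[ord])),
             rank = seq_along(ord), informative = m[ord] != 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Save / load a trained model as JSON
#'
#' @param model A `pwat_model`.
#' @param path JSON file path.
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pwat_model"))
  payload <- list(format_version = model$format_version,
                  feature_names = model$feature_names,
                  scaler = lapply(model$scaler, as.numeric),
                  intercept = model$intercept,
                  coefficients = as.numeric(model$coefficients),
                  alpha = model$alpha, config = model$config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  scaler <- structure(lapply(p$scaler, function(v) {
    v <- as.numeric(v); names(v) <- p$feature_names; v
  }), class = "robust_scaler")
  coefs <- as.numeric(p$coefficients)
  names(coefs) <- p$feature_names
  structure(list(scaler = scaler, intercept = p$intercept,
                 coefficients = coefs, alpha = p$alpha,
                 feature_names = p$feature_names, config = p$config,
                 format_version = p$format_version),
            class = "pwat_model")
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
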
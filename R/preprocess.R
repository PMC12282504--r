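# Preprocessing: age residualization of the brain block, column z-scoring of
# both blocks, the cross-block correlation matrix, and effective-rank
# estimation from an eigenvalue spectrum.
#
# All normalization parameters are estimated on a reference ("fit") subject
# subset and can be applied to held-out subjects, so that cross-validation
# never leaks test-set statistics into the training transform. The SD
# convention is the sample SD (denominator n - 1) throughout, which makes the
# cross-correlation matrix of the z-scored blocks exactly t(Zx) %*% Zy / (n-1).

# Simple linear regression of every column of X on age, via the closed-form
# normal equations (slope = cov(age, x)/var(age)).
age_fit <- function(X, age) {
  va <- var(age)
  if (!is.finite(va) || va == 0) stop_bbpls("age has zero variance")
  am <- mean(age)
  slope <- as.vector(crossprod(age - am, sweep(X, 2L, colMeans(X))) /
                       ((length(age) - 1) * va))
  intercept <- colMeans(X) - slope * am
  rbind(intercept = intercept, slope = slope)
}

age_apply <- function(X, age, coef) {
  X - rep(coef["intercept", ], each = nrow(X)) - outer(age, coef["slope", ])
}

#' Residualize brain columns on age
#'
#' Replaces each brain column by the residuals of a simple linear regression
#' of that column on age. Regression coefficients are fit on `fit_on` and
#' applied to all subjects, so held-out subjects can be corrected with
#' train-set coefficients. The behavior block is never age-corrected.
#'
#' @param ds a `study_dataset`.
#' @param fit_on integer or logical subject index used to fit the regressions
#'   (default: all subjects). At least 3 subjects; age must vary.
#' @return list with `brain_resid` (matrix) and `age_coef` (2 x p matrix of
#'   intercepts and slopes).
#' @export
residualize_age <- function(ds, fit_on = NULL) {
  fit_on <- fit_on %||% seq_along(ds$age)
  idx <- seq_along(ds$age)[fit_on]
  if (length(idx) < 3L) stop_bbpls("need at least 3 subjects to fit age regression")
  coef <- age_fit(ds$brain[idx, , drop = FALSE], ds$age[idx])
  list(brain_resid = age_apply(ds$brain, ds$age, coef), age_coef = coef)
}

#' Z-score matrix columns
#'
#' With `model = NULL`, per-column mean and sample SD (denominator n - 1) are
#' estimated from `X` itself and the standardized matrix has column means 0
#' and SDs 1. With a fitted model (as returned in `$model`), the stored
#' train-set parameters are applied instead (train-to-test transfer).
#'
#' @param X numeric matrix.
#' @param model optional list with `center` and `scale` vectors.
#' @return list with `Z` (standardized matrix) and `model`.
#' @export
zscore_columns <- function(X, model = NULL) {
  assert_matrix(X, "X")
  if (is.null(model)) {
    center <- colMeans(X)
    scale <- apply(X, 2L, sd)
    zero <- which(scale == 0)
    if (length(zero))
      stop_bbpls("zero-variance column: %s",
                 paste(colnames(X)[zero] %||% zero, collapse = ", "))
    model <- list(center = center, scale = scale)
  }
  Z <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  list(Z = Z, model = model)
}

#' Fit the full preprocessing model on a subject subset
#'
#' Fits age regressions for the brain block and z-scoring parameters for both
#' blocks on `fit_on`, returning a model that [apply_preprocess()] can apply
#' to any subject subset (including held-out subjects).
#'
#' @param ds a `study_dataset`.
#' @param fit_on subject index to estimate parameters on (default all).
#' @param age_correct residualize the brain block on age first (set `FALSE`
#'   when the imaging values were already age-corrected upstream).
#' @return an object of class `preprocess_model`.
#' @export
fit_preprocess <- function(ds, fit_on = NULL, age_correct = TRUE) {
  fit_on <- fit_on %||% seq_along(ds$age)
  idx <- seq_along(ds$age)[fit_on]
  if (length(idx) < 3L) stop_bbpls("need at least 3 subjects to fit preprocessing")
  coef <- if (age_correct) age_fit(ds$brain[idx, , drop = FALSE], ds$age[idx])
  Xr <- if (age_correct)
    age_apply(ds$brain[idx, , drop = FALSE], ds$age[idx], coef)
  else ds$brain[idx, , drop = FALSE]
  zx <- zscore_columns(Xr)
  zy <- zscore_columns(ds$behavior[idx, , drop = FALSE])
  structure(list(age_coef = coef, brain = zx$model, behavior = zy$model,
                 roi_names = ds$roi_names, behavior_names = ds$behavior_names),
            class = "preprocess_model")
}

#' Apply a fitted preprocessing model
#'
#' @param model a `preprocess_model` from [fit_preprocess()].
#' @param ds a `study_dataset` with the same columns.
#' @param rows subject index to transform (default all).
#' @return list with standardized matrices `Zx` and `Zy`.
#' @export
apply_preprocess <- function(model, ds, rows = NULL) {
  rows <- rows %||% seq_along(ds$age)
  idx <- seq_along(ds$age)[rows]
  if (!identical(model$roi_names, ds$roi_names) ||
      !identical(model$behavior_names, ds$behavior_names))
    stop_bbpls("preprocess_model columns do not match the dataset")
  Xr <- if (is.null(model$age_coef)) ds$brain[idx, , drop = FALSE]
  else age_apply(ds$brain[idx, , drop = FALSE], ds$age[idx], model$age_coef)
  list(Zx = zscore_columns(Xr, model$brain)$Z,
       Zy = zscore_columns(ds$behavior[idx, , drop = FALSE], model$behavior)$Z)
}

#' Cross-block correlation matrix
#'
#' Pearson correlation of every brain column with every behavior column
#' across subjects. For blocks standardized with the sample-SD convention
#' this equals `t(Zx) %*% Zy / (n - 1)`.
#'
#' @param Zx n x p standardized brain block.
#' @param Zy n x q standardized behavior block.
#' @return object of class `cross_correlation`: list with `R` (p x q) and `n`.
#' @export
cross_correlation <- function(Zx, Zy) {
  assert_matrix(Zx, "Zx"); assert_matrix(Zy, "Zy")
  if (nrow(Zx) != nrow(Zy))
    stop_bbpls("blocks have different subject counts (%d vs %d)",
               nrow(Zx), nrow(Zy))
  if (nrow(Zx) < 3L) stop_bbpls("need n >= 3 subjects")
  structure(list(R = cor(Zx, Zy), n = nrow(Zx)), class = "cross_correlation")
}

#' Effective number of independent variables
#'
#' Estimates how many effectively independent variables a correlated set
#' contains, from the eigenvalue spectrum of its M x M correlation matrix.
#' The default is the eigenvalue-variance estimator
#' `Meff = 1 + (M - 1) * (1 - Var(lambda) / M)` with the sample variance
#' (denominator M - 1); `method = "truncated"` instead sums per-eigenvalue
#' contributions `I(lambda >= 1) + (lambda - floor(lambda))`. Eigenvalues
#' that are numerically negative (non-PSD input) are clipped at 0 first.
#'
#' @param C symmetric correlation matrix with unit diagonal.
#' @param method `"eigen_variance"` (default) or `"truncated"`.
#' @return list with `value` (real) and `integer` (floor of value).
#' @export
effective_rank <- function(C, method = c("eigen_variance", "truncated")) {
  method <- match.arg(method)
  assert_matrix(C, "C")
  if (nrow(C) != ncol(C) || max(abs(C - t(C))) > 1e-8)
    stop_bbpls("C must be a symmetric square matrix")
  if (max(abs(diag(C) - 1)) > 1e-8)
    stop_bbpls("C must have unit diagonal")
  M <- nrow(C)
  lambda <- pmax(eigen(C, symmetric = TRUE, only.values = TRUE)$values, 0)
  value <- switch(method,
    eigen_variance = 1 + (M - 1) * (1 - var(lambda) / M),
    truncated = sum((lambda >= 1) + (lambda - floor(lambda)))
  )
  value <- min(max(value, 1), M)  # clamp floating-point epsilon overshoot
  list(value = value, integer = as.integer(floor(value)))
}
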
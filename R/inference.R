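# Nonparametric inference for the PLS decomposition:
#   (i)   permutation tests of the singular values (overall LV significance),
#   (ii)  bootstrap resampling of subjects (weight and loading reliability),
#   (iii) repeated random train/test splits (out-of-sample score correlation).
#
# Resampled decompositions are aligned to the observed one by an orthogonal
# Procrustes rotation before extraction, which resolves the sign and order
# indeterminacy of the SVD across resamples.

#' Orthogonal Procrustes alignment of singular vectors
#'
#' Returns `new %*% Q` where `Q` is the orthogonal matrix minimizing the
#' Frobenius distance to `ref` (computed from the SVD of `t(new) %*% ref`).
#' When the overlap between the two bases is numerically rank-deficient the
#' function falls back to per-column sign alignment (with a message).
#'
#' @param ref,new matrices of identical shape with (near-)orthonormal columns.
#' @return the aligned matrix, with the rotation in attribute `"rotation"`.
#' @export
procrustes_align <- function(ref, new) {
  if (!all(dim(ref) == dim(new)))
    stop_bbpls("ref and new must have identical shapes")
  M <- crossprod(new, ref)
  sv <- svd(M)
  if (min(sv$d) < 1e-10 * max(sv$d, 1)) {
    message("procrustes_align: rank-deficient overlap; falling back to per-column sign alignment")
    sgn <- sign(colSums(ref * new))
    sgn[sgn == 0] <- 1
    Q <- diag(sgn, ncol(new))
  } else {
    Q <- sv$u %*% t(sv$v)
  }
  out <- new %*% Q
  attr(out, "rotation") <- Q
  out
}

#' Permutation test of latent-variable significance
#'
#' Rows of the behavior block are randomly permuted (brain block fixed),
#' preprocessing is re-applied, the SVD is recomputed, and the permuted
#' singular values are matched to the observed components before the
#' exceedance counts are taken. P-values use the add-one rule
#' `p_i = (#\{perm S_i >= observed S_i\} + 1) / (n_permutations + 1)` and can
#' therefore never be exactly zero.
#'
#' Two matching schemes are available. `align = "position"` (default)
#' compares the i-th largest permuted singular value with the i-th observed
#' one; for LV-1 this is an exact max-statistic permutation test and is
#' type-I calibrated. `align = "procrustes"` rotates the permuted singular
#' structure onto the observed singular vectors and extracts per-component
#' aligned values (column norms of the rotated salience matrix); because the
#' rotated value for a leading component is a spectrum average while the
#' observed value is a spectrum maximum, this variant is strongly
#' anti-conservative for leading LVs under a global null and is provided for
#' comparability only (see the methods vignette).
#'
#' Note: column-wise z-scoring and age residualization are invariant to the
#' row order of the behavior block, so permuting the standardized rows is
#' exactly equivalent to re-preprocessing permuted raw data.
#'
#' @param ds the analysis `study_dataset` (typically the ED subsample).
#' @param config an [analysis_config()].
#' @param align permuted-to-observed matching scheme (see above).
#' @return object of class `bbpls_permutation`: `pvalues`, `observed_s`,
#'   `perm_s` (n_permutations x k), `n_permutations`, `align`, `seed`.
#' @export
permutation_test <- function(ds, config = analysis_config(),
                             align = c("position", "procrustes")) {
  align <- match.arg(align)
  n <- length(ds$subject_id)
  if (n < 3L) stop_bbpls("need n >= 3 subjects")
  model <- fit_preprocess(ds, age_correct = config$age_correct)
  Z <- apply_preprocess(model, ds)
  obs <- pls_decompose(cross_correlation(Z$Zx, Z$Zy), Z$Zx, Z$Zy)
  k <- length(obs$s)
  nperm <- config$n_permutations
  set.seed(substream_seed(config$seed, "permutation"))
  perm_s <- matrix(NA_real_, nperm, k)
  for (b in seq_len(nperm)) {
    Zy_p <- Z$Zy[sample.int(n), , drop = FALSE]
    Rp <- crossprod(Z$Zx, Zy_p) / (n - 1)
    if (align == "position") {
      perm_s[b, ] <- svd(Rp, nu = 0, nv = 0)$d[seq_len(k)]
    } else {
      svp <- svd(Rp, nu = k, nv = k)
      Vp <- procrustes_align(obs$v, svp$v)
      # Rotate the left structure with the same Q and read off the aligned
      # singular value of each observed component as a column norm.
      L <- svp$u %*% (svp$d[seq_len(k)] * attr(Vp, "rotation"))
      perm_s[b, ] <- sqrt(colSums(L^2))
    }
  }
  pvalues <- (colSums(perm_s >= rep(obs$s, each = nperm)) + 1) / (nperm + 1)
  structure(list(pvalues = pvalues, observed_s = obs$s, perm_s = perm_s,
                 n_permutations = nperm, align = align, seed = config$seed),
            class = "bbpls_permutation")
}

# Draw a bootstrap resample whose columns all retain variance (and whose ages
# vary); degenerate resamples are redrawn up to 10 times, then error.
draw_bootstrap_index <- function(ds, n) {
  for (attempt in 1:10) {
    idx <- sample.int(n, replace = TRUE)
    ok <- var(ds$age[idx]) > 0 &&
      all(matrixStats_colVars(ds$brain[idx, , drop = FALSE]) > 0) &&
      all(matrixStats_colVars(ds$behavior[idx, , drop = FALSE]) > 0)
    if (ok) return(idx)
    message("bootstrap: degenerate resample redrawn (attempt ", attempt, ")")
  }
  stop_bbpls("bootstrap: 10 consecutive degenerate resamples")
}

# Column variances without an extra dependency.
matrixStats_colVars <- function(X) {
  n <- nrow(X)
  (colSums(X^2) - n * colMeans(X)^2) / (n - 1)
}

#' Bootstrap reliability of weights and loadings
#'
#' Subjects are resampled with replacement; each resample is re-preprocessed
#' (age regression and z-scoring re-fit on the resample), re-decomposed, and
#' aligned to the original decomposition by a Procrustes rotation of the
#' stacked singular vectors. Weight reliability is summarized by bootstrap
#' ratios (original weight / bootstrap SE; interpretable as z-scores, with
#' `|BSR| > bsr_threshold` flagged reliable). Loading reliability uses
#' percentile confidence intervals: a loading whose interval crosses zero is
#' flagged non-reliable.
#'
#' The Procrustes rotation is computed on the leading `n_align` components
#' only (default: the largest requested CI component, at least 2), with the
#' trailing components sign-aligned per column. Rotating in the full
#' `min(p, q)`-dimensional basis would mix the many noise-level components
#' into the leading ones, which artificially stabilizes the resampled
#' leading weights, shrinks their bootstrap SEs and inflates the
#' false-positive rate of the `|BSR|` flags (see the methods vignette).
#'
#' @param ds the analysis `study_dataset`.
#' @param dec the observed `pls_decomposition` of `ds`.
#' @param config an [analysis_config()]; `n_bootstraps >= 50` is required
#'   for CI output.
#' @param ci_lvs latent variables for which loading CIs are computed
#'   (default: first two).
#' @param n_align size of the leading subspace aligned by Procrustes
#'   rotation.
#' @param store_draws keep the per-resample aligned weight draws (memory
#'   heavy; used by oracle tests).
#' @return object of class `bbpls_bootstrap`.
#' @export
bootstrap_analysis <- function(ds, dec, config = analysis_config(),
                               ci_lvs = NULL, n_align = NULL,
                               store_draws = FALSE) {
  n <- length(ds$subject_id)
  k <- length(dec$s)
  nB <- config$n_bootstraps
  if (nB < 50L) stop_bbpls("n_bootstraps must be >= 50 for CI output")
  ci_lvs <- as.integer(ci_lvs %||% seq_len(min(2L, k)))
  n_align <- min(k, as.integer(n_align %||% max(2L, max(ci_lvs))))
  p <- nrow(dec$u); q <- nrow(dec$v)
  ref <- rbind(dec$u, dec$v)

  sumU <- matrix(0, p, k); sumU2 <- matrix(0, p, k)
  sumV <- matrix(0, q, k); sumV2 <- matrix(0, q, k)
  m <- length(ci_lvs)
  draws_lx <- array(NA_real_, c(nB, p, m))
  draws_ly <- array(NA_real_, c(nB, q, m))
  draws_u <- if (store_draws) array(NA_real_, c(nB, p, k)) else NULL
  draws_v <- if (store_draws) array(NA_real_, c(nB, q, k)) else NULL

  lead <- seq_len(n_align)
  set.seed(substream_seed(config$seed, "bootstrap"))
  for (b in seq_len(nB)) {
    idx <- draw_bootstrap_index(ds, n)
    model <- fit_preprocess(ds, idx, age_correct = config$age_correct)
    Z <- apply_preprocess(model, ds, idx)
    Rb <- crossprod(Z$Zx, Z$Zy) / (n - 1)
    svb <- svd(Rb, nu = k, nv = k)
    stacked <- rbind(svb$u, svb$v)
    aligned <- stacked
    aligned[, lead] <- procrustes_align(ref[, lead, drop = FALSE],
                                        stacked[, lead, drop = FALSE])
    if (n_align < k) {
      trail <- (n_align + 1L):k
      sgn <- sign(colSums(ref[, trail, drop = FALSE] *
                            stacked[, trail, drop = FALSE]))
      sgn[sgn == 0] <- 1
      aligned[, trail] <- sweep(stacked[, trail, drop = FALSE], 2L, sgn, "*")
    }
    Ub <- aligned[seq_len(p), , drop = FALSE]
    Vb <- aligned[p + seq_len(q), , drop = FALSE]
    sumU <- sumU + Ub; sumU2 <- sumU2 + Ub^2
    sumV <- sumV + Vb; sumV2 <- sumV2 + Vb^2
    draws_lx[b, , ] <- cor(Z$Zx, Z$Zx %*% Ub[, ci_lvs, drop = FALSE])
    draws_ly[b, , ] <- cor(Z$Zy, Z$Zy %*% Vb[, ci_lvs, drop = FALSE])
    if (store_draws) { draws_u[b, , ] <- Ub; draws_v[b, , ] <- Vb }
  }

  boot_sd <- function(s, s2) {
    v <- pmax((s2 - s^2 / nB) / (nB - 1), 0)
    sqrt(v)
  }
  se_u <- boot_sd(sumU, sumU2); se_v <- boot_sd(sumV, sumV2)
  dimnames(se_u) <- dimnames(dec$u); dimnames(se_v) <- dimnames(dec$v)
  bsr_u <- dec$u / se_u; bsr_v <- dec$v / se_v

  alpha <- config$alpha
  loading_ci <- list()
  for (j in seq_along(ci_lvs)) {
    lv <- ci_lvs[j]
    qs_x <- apply(draws_lx[, , j, drop = FALSE], 2L, quantile,
                  probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
    qs_y <- apply(draws_ly[, , j, drop = FALSE], 2L, quantile,
                  probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
    tab <- data.frame(
      block = c(rep("brain", p), rep("behavior", q)),
      variable = c(rownames(dec$u), rownames(dec$v)),
      loading = c(dec$brain_loadings[, lv], dec$behavior_loadings[, lv]),
      lower = c(qs_x[1, ], qs_y[1, ]),
      upper = c(qs_x[2, ], qs_y[2, ]))
    tab$reliable <- tab$lower > 0 | tab$upper < 0
    loading_ci[[paste0("LV", lv)]] <- tab
  }

  structure(list(
    bootstrap_se_brain = se_u, bootstrap_se_behavior = se_v,
    bootstrap_ratios_brain = bsr_u, bootstrap_ratios_behavior = bsr_v,
    reliable_brain = abs(bsr_u) > config$bsr_threshold,
    reliable_behavior = abs(bsr_v) > config$bsr_threshold,
    loading_ci = loading_ci, ci_lvs = ci_lvs, n_align = n_align,
    n_bootstraps = nB, seed = config$seed,
    bsr_threshold = config$bsr_threshold,
    draws = if (store_draws) list(u = draws_u, v = draws_v) else NULL
  ), class = "bbpls_bootstrap")
}

# Train/test split indices, optionally stratified on subtype/group so class
# imbalance stays stable across test sets.
cv_split <- function(ds, train_fraction, stratify) {
  n <- length(ds$subject_id)
  strata <- if (stratify) {
    lab <- paste(ds$group, ifelse(is.na(ds$subtype), "none", as.character(ds$subtype)))
    split(seq_len(n), lab)
  } else list(seq_len(n))
  train <- unlist(lapply(strata, function(ix) {
    ntr <- round(train_fraction * length(ix))
    ntr <- max(1L, min(length(ix) - 1L, ntr))
    ix[sample.int(length(ix), ntr)]
  }), use.names = FALSE)
  sort(train)
}

cv_run <- function(ds, config, lv) {
  n <- length(ds$subject_id)
  rs <- numeric(config$n_cv_splits)
  for (s in seq_len(config$n_cv_splits)) {
    train <- cv_split(ds, config$train_fraction, config$stratify_cv)
    test <- setdiff(seq_len(n), train)
    if (length(test) < 3L)
      stop_bbpls("test split has %d subjects; need at least 3 (increase n or lower train_fraction)",
                 length(test))
    model <- fit_preprocess(ds, train, age_correct = config$age_correct)
    Ztr <- apply_preprocess(model, ds, train)
    dec_tr <- pls_decompose(cross_correlation(Ztr$Zx, Ztr$Zy), Ztr$Zx, Ztr$Zy)
    Zte <- apply_preprocess(model, ds, test)
    pr <- project_scores(Zte$Zx, Zte$Zy, dec_tr, lv)
    rs[s] <- cor(pr$brain_scores, pr$behavior_scores)
  }
  rs
}

#' Out-of-sample validation by repeated random splits
#'
#' For each split, preprocessing parameters and the decomposition are fit on
#' the training subjects only; held-out subjects are projected onto the
#' train-fitted weights, and the Pearson correlation between their brain and
#' behavior scores is recorded. The reported summary is the mean out-of-sample
#' correlation across splits. When `config$n_cv_null > 0`, a permutation
#' p-value is attached by repeating the *entire* split procedure on datasets
#' with behavior rows permuted:
#' `p = (#\{null mean r >= observed mean r\} + 1) / (n_cv_null + 1)`.
#'
#' @param ds the analysis `study_dataset`.
#' @param config an [analysis_config()].
#' @param lv latent-variable index to validate.
#' @return object of class `bbpls_cv`: `split_rs`, `mean_r`, `pvalue`,
#'   `n_splits`, `lv`.
#' @export
cross_validate <- function(ds, config = analysis_config(), lv = 1L) {
  set.seed(substream_seed(config$seed, "cv"))
  split_rs <- cv_run(ds, config, lv)
  mean_r <- mean(split_rs)
  pvalue <- NULL
  if (config$n_cv_null > 0L) {
    set.seed(substream_seed(config$seed, "cv_null"))
    n <- length(ds$subject_id)
    null_means <- numeric(config$n_cv_null)
    for (r in seq_len(config$n_cv_null)) {
      ds_p <- ds
      ds_p$behavior <- ds$behavior[sample.int(n), , drop = FALSE]
      null_means[r] <- mean(cv_run(ds_p, config, lv))
    }
    pvalue <- (sum(null_means >= mean_r) + 1) / (config$n_cv_null + 1)
  }
  structure(list(split_rs = split_rs, mean_r = mean_r, pvalue = pvalue,
                 n_splits = config$n_cv_splits, lv = as.integer(lv),
                 seed = config$seed),
            class = "bbpls_cv")
}
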
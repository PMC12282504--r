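# Core PLS-correlation decomposition: SVD of the cross-block correlation
# matrix into latent variables (LVs). Each LV pairs a brain weight vector
# (left singular vector), a behavior weight vector (right singular vector)
# and a singular value; squared singular values, normalized to their total,
# give the fraction of cross-block covariance each LV explains. Subject
# scores are the projections of the z-scored blocks onto the weights;
# loadings are the Pearson correlations of each original column with its own
# block's scores.

# SVD sign is arbitrary per component. Convention: flip (u_k, v_k) jointly so
# the behavior loading largest in absolute value is positive. Joint flipping
# leaves the brain-behavior score correlation unchanged.
apply_sign_convention <- function(u, v, Zy) {
  for (k in seq_len(ncol(v))) {
    ld <- cor(Zy, Zy %*% v[, k])
    if (ld[which.max(abs(ld))] < 0) {
      u[, k] <- -u[, k]
      v[, k] <- -v[, k]
    }
  }
  list(u = u, v = v)
}

#' Decompose a cross-correlation matrix into latent variables
#'
#' Runs a full SVD of the p x q cross-correlation matrix and derives, for all
#' `k = min(p, q)` components: singular values (descending), fractions of
#' covariance explained, per-subject brain and behavior scores, and loadings
#' (correlations of each column with its block's scores). A deterministic
#' sign convention is applied: each component is jointly flipped so that the
#' largest-magnitude behavior loading is positive.
#'
#' @param R a `cross_correlation` (or bare p x q matrix).
#' @param Zx,Zy the standardized blocks `R` was computed from.
#' @return an object of class `pls_decomposition` with fields `u` (p x k),
#'   `v` (q x k), `s`, `covexp`, `brain_scores`, `behavior_scores`,
#'   `brain_loadings`, `behavior_loadings`.
#' @export
pls_decompose <- function(R, Zx, Zy) {
  Rm <- if (inherits(R, "cross_correlation")) R$R else R
  assert_matrix(Rm, "R")
  if (all(Rm == 0)) stop_bbpls("no covariance structure: R is all zeros")
  if (ncol(Zx) != nrow(Rm) || ncol(Zy) != ncol(Rm))
    stop_bbpls("block dimensions do not match R")
  k <- min(dim(Rm))
  sv <- svd(Rm, nu = k, nv = k)
  flip <- apply_sign_convention(sv$u, sv$v, Zy)
  u <- flip$u; v <- flip$v
  rownames(u) <- colnames(Zx); rownames(v) <- colnames(Zy)
  brain_scores <- Zx %*% u
  behavior_scores <- Zy %*% v
  structure(list(
    u = u, v = v, s = sv$d[seq_len(k)],
    covexp = covariance_explained(sv$d[seq_len(k)]),
    brain_scores = brain_scores, behavior_scores = behavior_scores,
    brain_loadings = cor(Zx, brain_scores),
    behavior_loadings = cor(Zy, behavior_scores)
  ), class = "pls_decomposition")
}

#' @export
print.pls_decomposition <- function(x, ...) {
  k <- length(x$s)
  cat(sprintf("pls_decomposition: %d latent variables (p = %d, q = %d)\n",
              k, nrow(x$u), nrow(x$v)))
  show <- head(seq_len(k), 5L)
  for (i in show)
    cat(sprintf("  LV%-2d singular value %.4f  covariance explained %5.1f%%\n",
                i, x$s[i], 100 * x$covexp[i]))
  if (k > 5L) cat(sprintf("  ... and %d more\n", k - 5L))
  invisible(x)
}

#' Fraction of cross-block covariance explained per latent variable
#'
#' @param s non-negative singular values.
#' @return vector `s^2 / sum(s^2)`; sums to 1 over all components.
#' @export
covariance_explained <- function(s) {
  if (any(s < 0)) stop_bbpls("singular values must be non-negative")
  tot <- sum(s^2)
  if (tot == 0) stop_bbpls("all singular values are zero")
  s^2 / tot
}

#' Project (held-out) subjects onto a latent variable
#'
#' The new blocks must be standardized with the *training* preprocessing
#' model so no test-set statistics enter the transform.
#'
#' @param Zx_new,Zy_new standardized blocks for new subjects.
#' @param dec a `pls_decomposition` fitted on the training subjects.
#' @param lv latent-variable index.
#' @return list with numeric vectors `brain_scores` and `behavior_scores`.
#' @export
project_scores <- function(Zx_new, Zy_new, dec, lv = 1L) {
  if (ncol(Zx_new) != nrow(dec$u) || ncol(Zy_new) != nrow(dec$v))
    stop_bbpls("column counts of the new blocks do not match the decomposition")
  if (lv < 1L || lv > length(dec$s)) stop_bbpls("lv out of range")
  list(brain_scores = as.vector(Zx_new %*% dec$u[, lv]),
       behavior_scores = as.vector(Zy_new %*% dec$v[, lv]))
}

#' Correlation between brain and behavior scores
#'
#' Pearson correlation with a two-sided parametric p-value.
#'
#' @param brain_scores,behavior_scores numeric vectors of equal length >= 3.
#' @return list with `r`, `p`, `n`.
#' @export
score_correlation <- function(brain_scores, behavior_scores) {
  if (length(brain_scores) != length(behavior_scores) || length(brain_scores) < 3L)
    stop_bbpls("score vectors must have equal length >= 3")
  if (sd(brain_scores) == 0 || sd(behavior_scores) == 0)
    stop_bbpls("zero variance in a score vector")
  ct <- cor.test(brain_scores, behavior_scores)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(brain_scores))
}
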